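#' Read a two-row-per-individual STRUCTURE genotype file
#'
#' Expects one header row of locus names, then two rows per individual, each
#' holding the individual label, an integer population code and one allele
#' code per locus. `missing_code` (default -9) marks missing alleles. Allele
#' pairs are collapsed to 0/1/2 dosages counting copies of the alternate
#' allele, where the reference allele at a locus is the lexically smaller
#' observed allele code. A locus with more than two distinct allele codes is
#' an error.
#'
#' @param path file path
#' @param pop_meta optional data frame mapping the file's integer population
#'   codes to labels: columns `pop_id`, `population`, and optionally
#'   `lineage` and `species`. When omitted, populations are named
#'   `pop<k>` and each is its own lineage.
#' @param missing_code allele code meaning missing (default -9)
#' @return a [genotype_matrix()]
#' @export
read_structure <- function(path, pop_meta = NULL, missing_code = -9) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("STRUCTURE file too short: ", path)
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  n_loci <- length(header)
  body <- lines[-1]
  if (length(body) %% 2 != 0)
    stop("odd number of genotype rows (", length(body),
         "): two rows per individual required")
  n_ind <- length(body) / 2

  parse_row <- function(i) {
    f <- strsplit(trimws(body[i]), "[ \t]+")[[1]]
    if (length(f) != n_loci + 2)
      stop("line ", i + 1, ": expected ", n_loci + 2, " fields, found ",
           length(f))
    f
  }

  ids <- character(n_ind)
  pops <- character(n_ind)
  a1 <- matrix("", n_ind, n_loci)
  a2 <- matrix("", n_ind, n_loci)
  for (k in seq_len(n_ind)) {
    r1 <- parse_row(2 * k - 1)
    r2 <- parse_row(2 * k)
    if (r1[1] != r2[1])
      stop("lines ", 2 * k, "-", 2 * k + 1,
           ": the two rows of an individual have different labels ('",
           r1[1], "' vs '", r2[1], "')")
    ids[k] <- r1[1]
    pops[k] <- r1[2]
    a1[k, ] <- r1[-(1:2)]
    a2[k, ] <- r2[-(1:2)]
  }

  miss <- as.character(missing_code)
  geno <- matrix(NA_integer_, n_ind, n_loci)
  for (l in seq_len(n_loci)) {
    al <- c(a1[, l], a2[, l])
    obs <- sort(unique(al[al != miss]))
    if (length(obs) > 2)
      stop("locus '", header[l], "' has ", length(obs),
           " distinct allele codes (biallelic required): ",
           paste(obs, collapse = ", "))
    ref <- if (length(obs)) obs[1] else miss
    dos <- (a1[, l] != ref) + (a2[, l] != ref)
    dos[a1[, l] == miss | a2[, l] == miss] <- NA_integer_
    geno[, l] <- as.integer(dos)
  }
  rownames(geno) <- make.unique(ids)
  colnames(geno) <- header

  if (is.null(pop_meta)) {
    pop_label <- paste0("pop", pops)
    meta <- NULL
  } else {
    pm <- as.data.frame(pop_meta, stringsAsFactors = FALSE)
    if (!all(c("pop_id", "population") %in% names(pm)))
      stop("pop_meta must have columns pop_id and population")
    m <- match(pops, as.character(pm$pop_id))
    if (anyNA(m))
      stop("population codes without metadata: ",
           paste(unique(pops[is.na(m)]), collapse = ", "))
    pop_label <- pm$population[m]
    meta <- data.frame(
      population = pm$population,
      lineage = if ("lineage" %in% names(pm)) pm$lineage else pm$population,
      species = if ("species" %in% names(pm)) pm$species else "sp",
      stringsAsFactors = FALSE)
  }
  genotype_matrix(geno, pop_label, meta)
}

#' Write a genotype matrix as a two-row-per-individual STRUCTURE file
#'
#' Alleles are coded 1 (reference) and 2 (alternate); missing entries are
#' written as `missing_code` on both rows. Population labels are written as
#' integer codes in the order of the factor levels; the label-to-code map is
#' returned invisibly (and can be passed back to [read_structure()] as
#' `pop_meta`).
#'
#' @param g a [genotype_matrix()]
#' @param path output file path
#' @param missing_code allele code for missing data (default -9)
#' @return invisibly, the `pop_meta` data frame (with `pop_id`)
#' @export
write_structure <- function(g, path, missing_code = -9) {
  stopifnot(inherits(g, "genotype_matrix"))
  geno <- g$geno
  pop_id <- as.integer(g$population)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(geno), collapse = "\t"), con)
  n_loci <- ncol(geno)
  for (k in seq_len(nrow(geno))) {
    dos <- geno[k, ]
    r1 <- ifelse(is.na(dos), missing_code, ifelse(dos >= 1, 2L, 1L))
    r2 <- ifelse(is.na(dos), missing_code, ifelse(dos == 2, 2L, 1L))
    writeLines(paste(c(rownames(geno)[k], pop_id[k], r1), collapse = "\t"), con)
    writeLines(paste(c(rownames(geno)[k], pop_id[k], r2), collapse = "\t"), con)
  }
  meta <- merge(data.frame(pop_id = seq_along(levels(g$population)),
                           population = levels(g$population),
                           stringsAsFactors = FALSE),
                g$pop_meta, by = "population", sort = FALSE)
  meta <- meta[order(meta$pop_id), c("pop_id", "population", "lineage", "species")]
  rownames(meta) <- NULL
  invisible(meta)
}

#' Read or write a long-form CSV genotype table
#'
#' Columns: `individual`, `population`, `locus`, `dosage` (0/1/2, empty for
#' missing). A plain interchange format for spreadsheets and joins.
#'
#' @param g a [genotype_matrix()]
#' @param path file path
#' @return `write_genotype_csv` returns `path` invisibly;
#'   `read_genotype_csv` returns a [genotype_matrix()]
#' @export
write_genotype_csv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  long <- data.frame(
    individual = rep(rownames(g$geno), times = ncol(g$geno)),
    population = rep(as.character(g$population), times = ncol(g$geno)),
    locus = rep(colnames(g$geno), each = nrow(g$geno)),
    dosage = as.vector(g$geno))
  write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_genotype_csv
#' @param pop_meta optional population metadata (see [genotype_matrix()])
#' @export
read_genotype_csv <- function(path, pop_meta = NULL) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  ind <- unique(long$individual)
  loc <- unique(long$locus)
  geno <- matrix(NA_integer_, length(ind), length(loc),
                 dimnames = list(ind, loc))
  geno[cbind(match(long$individual, ind), match(long$locus, loc))] <-
    as.integer(long$dosage)
  pop <- long$population[match(ind, long$individual)]
  genotype_matrix(geno, pop, pop_meta)
}
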