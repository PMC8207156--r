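#' Diploid biallelic SNP genotype matrix with population metadata
#'
#' The central container of the package: an individuals x loci matrix of
#' alternate-allele dosages (0, 1, 2, or `NA` for missing) together with the
#' population each individual belongs to and the lineage / species each
#' population belongs to.
#'
#' @param geno integer matrix, individuals in rows, loci in columns; entries
#'   in `{0, 1, 2}` or `NA`. Row names are individual ids (generated if
#'   absent), column names are locus names.
#' @param population character or factor of length `nrow(geno)`: population
#'   label per individual.
#' @param pop_meta data frame with columns `population`, `lineage`,
#'   `species`, one row per population. If omitted, each population is its
#'   own lineage and all share species `"sp"`.
#'
#' @return an object of class `genotype_matrix`: a list with elements
#'   `geno`, `population` (factor) and `pop_meta`.
#' @export
genotype_matrix <- function(geno, population, pop_meta = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad))
    stop("genotype codes outside {0, 1, 2, NA} at ", sum(bad), " entries")
  if (length(population) != nrow(geno))
    stop("population labels must match the number of individuals")
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("ind%03d", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("L%04d", seq_len(ncol(geno)))
  population <- factor(as.character(population))
  if (is.null(pop_meta)) {
    pop_meta <- data.frame(population = levels(population),
                           lineage = levels(population),
                           species = "sp",
                           stringsAsFactors = FALSE)
  }
  pop_meta <- as.data.frame(pop_meta, stringsAsFactors = FALSE)
  need <- c("population", "lineage", "species")
  if (!all(need %in% names(pop_meta)))
    stop("pop_meta must have columns population, lineage, species")
  pop_meta$population <- as.character(pop_meta$population)
  if (anyDuplicated(pop_meta$population))
    stop("duplicated population in pop_meta")
  missing_pop <- setdiff(levels(population), pop_meta$population)
  if (length(missing_pop))
    stop("populations without metadata: ", paste(missing_pop, collapse = ", "))
  pop_meta <- pop_meta[pop_meta$population %in% levels(population), , drop = FALSE]
  rownames(pop_meta) <- NULL
  structure(list(geno = geno, population = population, pop_meta = pop_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "individuals x", ncol(x$geno),
      "loci\n")
  cat("  populations:", paste(levels(x$population), collapse = ", "), "\n")
  cat("  lineages:   ", paste(unique(x$pop_meta$lineage), collapse = ", "), "\n")
  cat("  missing:    ",
      sprintf("%.2f%%", 100 * mean(is.na(x$geno))), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Restrict a genotype matrix to a subset of loci
#'
#' @param g a [genotype_matrix()]
#' @param loci logical, integer or character index into the locus columns
#' @return a `genotype_matrix` with the selected loci, labels preserved
#' @export
subset_loci <- function(g, loci) {
  stopifnot(inherits(g, "genotype_matrix"))
  g$geno <- g$geno[, loci, drop = FALSE]
  g
}

#' Restrict a genotype matrix to a subset of individuals
#'
#' @param g a [genotype_matrix()]
#' @param ind logical, integer or character index into the individual rows
#' @return a `genotype_matrix` with the selected individuals; population
#'   levels are dropped if emptied
#' @export
subset_individuals <- function(g, ind) {
  stopifnot(inherits(g, "genotype_matrix"))
  g$geno <- g$geno[ind, , drop = FALSE]
  g$population <- droplevels(g$population[ind])
  g$pop_meta <- g$pop_meta[g$pop_meta$population %in% levels(g$population), ,
                           drop = FALSE]
  rownames(g$pop_meta) <- NULL
  g
}

#' Lineage label per individual
#' @param g a [genotype_matrix()]
#' @return character vector of lineage labels, one per individual
#' @export
lineage_of_individuals <- function(g) {
  m <- setNames(g$pop_meta$lineage, g$pop_meta$population)
  unname(m[as.character(g$population)])
}

#' Species label per individual
#' @param g a [genotype_matrix()]
#' @return character vector of species labels, one per individual
#' @export
species_of_individuals <- function(g) {
  m <- setNames(g$pop_meta$species, g$pop_meta$population)
  unname(m[as.character(g$population)])
}

# grouping factor for "population" | "lineage" | "species"
group_factor <- function(g, grouping) {
  switch(grouping,
         population = g$population,
         lineage = factor(lineage_of_individuals(g)),
         species = factor(species_of_individuals(g)),
         stop("unknown grouping: ", grouping))
}
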