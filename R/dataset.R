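#' Construct a genotype dataset
#'
#' The package's central container: diploid integer allele calls for
#' `N` individuals at `L` loci, stored as two `N x L` integer matrices (one
#' per chromosome copy) with `NA` for missing calls, plus the population
#' assignment of every individual. SNP datasets code alleles 0/1 (derived
#' allele 1); microsatellite datasets code repeat counts.
#'
#' @param pop factor (or character) of population ids, one per individual.
#' @param a1,a2 integer matrices of first/second allele calls, `N x L`.
#' @param loci locus ids (default `locus<k>`).
#' @param ind individual ids (default `<pop>_<i>`).
#' @param type `"snp"` or `"microsat"`.
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(pop, a1, a2, loci = NULL, ind = NULL,
                             type = c("snp", "microsat")) {
  type <- match.arg(type)
  pop <- if (is.factor(pop)) droplevels(pop) else factor(pop, levels = unique(pop))
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2))) stop("allele matrices must have equal dimensions")
  if (nrow(a1) != length(pop)) stop("one row of allele calls per individual required")
  if (any(tabulate(pop) < 1L)) stop("every population needs at least one individual")
  if (any(a1 < 0L, na.rm = TRUE) || any(a2 < 0L, na.rm = TRUE))
    stop("allele codes must be non-negative or missing")
  if (is.null(loci)) loci <- sprintf("locus%d", seq_len(ncol(a1)))
  if (is.null(ind)) {
    idx <- stats::ave(seq_along(pop), pop, FUN = seq_along)
    ind <- sprintf("%s_%d", as.character(pop), idx)
  }
  dimnames(a1) <- dimnames(a2) <- list(ind, loci)
  structure(list(pop = pop, ind = ind, loci = loci, a1 = a1, a2 = a2,
                 ploidy = 2L, type = type),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset (%s): %d individuals in %d populations, %d loci\n",
              x$type, length(x$pop), nlevels(x$pop), length(x$loci)))
  miss <- sum(is.na(x$a1) | is.na(x$a2))
  cat(sprintf("  missing genotype calls: %d (%.2f%%)\n",
              miss, 100 * miss / length(x$a1)))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) {
  c(populations = nlevels(x$pop), individuals = length(x$pop), loci = length(x$loci))
}

n_pops <- function(x) nlevels(x$pop)
pop_ids <- function(x) levels(x$pop)

# TRUE where the individual is typed (both allele calls present)
typed_mask <- function(x) !is.na(x$a1) & !is.na(x$a2)

is_pooled <- function(x) inherits(x, "pool_dataset")

# rowsum() by population with rows guaranteed in factor-level order
pop_rowsum <- function(x, pop) {
  m <- rowsum(x, pop, na.rm = TRUE)
  m[match(levels(pop), rownames(m)), , drop = FALSE]
}

#' Collapse genotypes to per-population allele counts
#'
#' Discards individual identity, keeping per-population, per-locus allele
#' counts, as in pooled-DNA sequencing designs. Observed heterozygosity and
#' FIS are undefined downstream for pooled data. Missing genotype calls
#' contribute nothing; a population with no typed individuals at a locus has
#' total count 0 there.
#'
#' @param dataset a [genotype_dataset()].
#' @return an object of class `pool_dataset` with elements `counts` (named
#'   list, one `n_pops x n_loci` count matrix per allele code), `tot`
#'   (`n_pops x n_loci` total allele counts), `alleles`, `pop_ids`, `loci`.
#' @export
pool_frequencies <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  ok <- typed_mask(dataset)
  av <- sort(unique(c(dataset$a1[ok], dataset$a2[ok])))
  pop <- dataset$pop
  counts <- lapply(av, function(a) {
    pop_rowsum((dataset$a1 == a & ok) + (dataset$a2 == a & ok), pop)
  })
  names(counts) <- as.character(av)
  tot <- if (length(counts)) Reduce("+", counts) else
    matrix(0L, nlevels(pop), length(dataset$loci))
  dimnames(tot) <- list(levels(pop), dataset$loci)
  counts <- lapply(counts, function(m) { dimnames(m) <- dimnames(tot); m })
  structure(list(counts = counts, tot = tot, alleles = av,
                 pop_ids = levels(pop), loci = dataset$loci,
                 type = dataset$type),
            class = "pool_dataset")
}

#' @export
print.pool_dataset <- function(x, ...) {
  cat(sprintf("pool_dataset (%s): %d populations, %d loci, %d distinct alleles\n",
              x$type, length(x$pop_ids), length(x$loci), length(x$alleles)))
  invisible(x)
}
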