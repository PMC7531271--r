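#' Write a SNP dataset as VCF
#'
#' Plain-text VCF 4.2 with biallelic records (REF `A`, ALT `T`, GT field
#' only) and sample names `<pop>_<ind>`, so the population assignment
#' round-trips through the default naming convention. Missing genotypes are
#' written `./.`.
#'
#' @param dataset a SNP [genotype_dataset()].
#' @param path output path (`.vcf`).
#' @export
write_vcf <- function(dataset, path) {
  stopifnot(inherits(dataset, "genotype_dataset"), dataset$type == "snp")
  g1 <- ifelse(is.na(dataset$a1), ".", as.character(dataset$a1))
  g2 <- ifelse(is.na(dataset$a2), ".", as.character(dataset$a2))
  gt <- matrix(paste(g1, g2, sep = "/"), nrow = nrow(dataset$a1))
  gt[is.na(dataset$a1) | is.na(dataset$a2)] <- "./."
  body <- cbind("1", seq_along(dataset$loci), dataset$loci, "A", "T", ".",
                "PASS", ".", "GT", t(gt))
  lines <- c("##fileformat=VCFv4.2",
             "##source=popsampling",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", dataset$ind), collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Load genotypes from VCF or CSV
#'
#' * `"vcf"`: biallelic SNP records with a GT field (via the vcfR parser);
#'   multi-allelic records are skipped and their count reported; `./.` maps
#'   to missing. Populations come from the sample-name convention
#'   `<pop>_<ind>` unless `pop_map` (data frame or CSV path with columns
#'   `ind`, `pop`) overrides it.
#' * `"csv_genotypes"`: microsatellite-style table with columns `pop`, `ind`,
#'   then one column per locus holding `"a1/a2"` allele pairs (`"."`
#'   missing).
#' * `"csv_pool"`: pooled allele counts, columns `pop`, `locus`, `allele`,
#'   `count`.
#'
#' @param path input file.
#' @param format one of `"vcf"`, `"csv_genotypes"`, `"csv_pool"`.
#' @param pop_map optional individual-to-population mapping.
#' @return a [genotype_dataset()] (or `pool_dataset` for `"csv_pool"`).
#' @export
load_genotypes <- function(path, format = c("vcf", "csv_genotypes", "csv_pool"),
                           pop_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         vcf = load_vcf(path, pop_map),
         csv_genotypes = load_csv_genotypes(path),
         csv_pool = load_csv_pool(path))
}

load_vcf <- function(path, pop_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    message(sum(multi), " multi-allelic record(s) skipped")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- vcfR::getID(v)
  ids[is.na(ids) | ids == "."] <- sprintf("locus%d", which(is.na(ids) | ids == "."))
  samples <- colnames(gt)
  a1 <- sub("^([^/|]*)[/|].*$", "\\1", gt)
  a2 <- sub("^[^/|]*[/|](.*)$", "\\1", gt)
  to_int <- function(x) {
    x[x == "." | is.na(x)] <- NA
    suppressWarnings(matrix(as.integer(x), nrow = nrow(gt)))
  }
  a1 <- to_int(a1); a2 <- to_int(a2)
  pop <- sample_populations(samples, pop_map)
  genotype_dataset(pop, t(a1), t(a2), loci = ids, ind = samples, type = "snp")
}

sample_populations <- function(samples, pop_map = NULL) {
  if (!is.null(pop_map)) {
    if (is.character(pop_map)) pop_map <- utils::read.csv(pop_map,
                                                          stringsAsFactors = FALSE)
    if (!all(c("ind", "pop") %in% names(pop_map)))
      stop("pop_map needs columns ind, pop")
    idx <- match(samples, pop_map$ind)
    if (anyNA(idx))
      stop("sample(s) without population mapping: ",
           paste(samples[is.na(idx)], collapse = ", "))
    return(factor(pop_map$pop[idx], levels = unique(pop_map$pop[idx])))
  }
  if (!all(grepl("_", samples)))
    stop("sample(s) without population mapping: ",
         paste(samples[!grepl("_", samples)], collapse = ", "),
         " (expected \"<pop>_<ind>\" names or a pop_map)")
  pop <- sub("_[^_]*$", "", samples)
  factor(pop, levels = unique(pop))
}

#' Write genotypes as a CSV table
#'
#' Columns `pop`, `ind`, then one column per locus holding `"a1/a2"` allele
#' pairs, `"."` for missing -- the microsatellite exchange format.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path.
#' @export
write_genotypes_csv <- function(dataset, path) {
  cells <- matrix(paste(dataset$a1, dataset$a2, sep = "/"),
                  nrow = nrow(dataset$a1))
  cells[is.na(dataset$a1) | is.na(dataset$a2)] <- "."
  df <- data.frame(pop = as.character(dataset$pop), ind = dataset$ind,
                   cells, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("pop", "ind", dataset$loci)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

load_csv_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("pop", "ind") %in% names(df)))
    stop("genotype CSV needs pop and ind columns")
  loci <- setdiff(names(df), c("pop", "ind"))
  parse_allele <- function(x, which) {
    out <- rep(NA_character_, length(x))
    ok <- !is.na(x) & x != "." & grepl("/", x)
    parts <- strsplit(x[ok], "/", fixed = TRUE)
    out[ok] <- vapply(parts, `[`, "", which)
    out[out == "."] <- NA
    suppressWarnings(as.integer(out))
  }
  a1 <- sapply(loci, function(l) parse_allele(df[[l]], 1L))
  a2 <- sapply(loci, function(l) parse_allele(df[[l]], 2L))
  if (is.null(dim(a1))) { a1 <- rbind(a1); a2 <- rbind(a2) }
  type <- if (all(a1 %in% c(0L, 1L, NA), a2 %in% c(0L, 1L, NA))) "snp" else "microsat"
  genotype_dataset(factor(df$pop, levels = unique(df$pop)), a1, a2,
                   loci = loci, ind = df$ind, type = type)
}

#' Write pooled allele counts as CSV
#'
#' Long format: `pop`, `locus`, `allele`, `count` (zero-count combinations
#' omitted; all-missing cells therefore appear as absent rows, i.e. total 0).
#'
#' @param pool a [pool_frequencies()] result.
#' @param path output path.
#' @export
write_pool_csv <- function(pool, path) {
  stopifnot(inherits(pool, "pool_dataset"))
  rows <- lapply(names(pool$counts), function(a) {
    cm <- pool$counts[[a]]
    idx <- which(cm > 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(pop = pool$pop_ids[idx[, 1]], locus = pool$loci[idx[, 2]],
               allele = as.integer(a), count = cm[idx],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$pop, df$locus, df$allele), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

load_csv_pool <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pop", "locus", "allele", "count")
  if (!all(need %in% names(df))) stop("pool CSV needs columns ",
                                      paste(need, collapse = ", "))
  pops <- unique(df$pop)
  loci <- unique(df$locus)
  av <- sort(unique(df$allele))
  counts <- lapply(av, function(a) {
    m <- matrix(0L, length(pops), length(loci),
                dimnames = list(pops, loci))
    sel <- df$allele == a
    m[cbind(match(df$pop[sel], pops), match(df$locus[sel], loci))] <-
      as.integer(df$count[sel])
    m
  })
  names(counts) <- as.character(av)
  tot <- Reduce("+", counts)
  type <- if (all(av %in% c(0L, 1L))) "snp" else "microsat"
  structure(list(counts = counts, tot = tot, alleles = av,
                 pop_ids = pops, loci = loci, type = type),
            class = "pool_dataset")
}

#' Write / load population metadata
#'
#' CSV with columns `pop_id`, coordinates (`lon`/`lat`, or `x`/`y` for
#' planar synthetic landscapes), environmental values `env_*`, and any
#' derived columns (`pc1`, centroid distances).
#'
#' @param metadata data frame of population metadata.
#' @param path file path.
#' @rdname metadata-io
#' @export
write_metadata <- function(metadata, path) {
  md <- metadata
  md$planar <- if (is_planar(metadata)) 1L else 0L
  utils::write.csv(md, path, row.names = FALSE)
  invisible(path)
}

#' @rdname metadata-io
#' @export
load_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"pop_id" %in% names(df)) stop("metadata needs a pop_id column")
  planar <- "planar" %in% names(df) && any(df$planar == 1L)
  df$planar <- NULL
  coord_cols <- if (planar) c("x", "y") else
    intersect(c("lon", "lat", "x", "y"), names(df))
  if (length(coord_cols) < 2L) stop("metadata needs coordinate columns")
  for (cc in coord_cols) {
    bad <- which(!is.na(df[[cc]]) & is.na(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad))
      stop("non-numeric coordinate in column ", cc, ", row ",
           paste(bad, collapse = ", "))
    df[[cc]] <- as.numeric(df[[cc]])
  }
  if (anyDuplicated(df$pop_id))
    stop("duplicated population id(s): ",
         paste(unique(df$pop_id[duplicated(df$pop_id)]), collapse = ", "))
  attr(df, "planar") <- planar
  df
}

#' Validate metadata against a dataset
#'
#' Requires exactly one metadata row per dataset population; extra or
#' missing populations are named in the error.
#'
#' @param metadata a metadata data frame.
#' @param dataset a [genotype_dataset()] or `pool_dataset`.
#' @return the metadata, reordered to the dataset's population order.
#' @export
validate_metadata <- function(metadata, dataset) {
  ids <- pop_ids_of(dataset)
  extra <- setdiff(metadata$pop_id, ids)
  missing <- setdiff(ids, metadata$pop_id)
  if (length(extra)) stop("metadata rows for unknown population(s): ",
                          paste(extra, collapse = ", "))
  if (length(missing)) stop("metadata missing population(s): ",
                            paste(missing, collapse = ", "))
  out <- metadata[match(ids, metadata$pop_id), , drop = FALSE]
  attr(out, "planar") <- attr(metadata, "planar")
  rownames(out) <- NULL
  out
}

#' Tidy CSV export of summary statistics
#'
#' Writes the per-locus, per-population table (locus, pop, n, Ho, Hs, FIS)
#' of a [basic_stats()] result.
#'
#' @param stats a `summary_stats` object.
#' @param path output path.
#' @export
write_stats_csv <- function(stats, path) {
  P <- nrow(stats$hs); L <- ncol(stats$hs)
  df <- data.frame(
    locus = rep(colnames(stats$hs), each = P),
    pop = rep(rownames(stats$hs), L),
    n = as.vector(stats$n),
    ho = as.vector(stats$ho),
    hs = as.vector(stats$hs),
    fis = as.vector(stats$fis),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
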