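#' Construct a genotype matrix
#'
#' The central container of the package: an `n x m` matrix of biallelic SNP
#' dosages (ALT-allele counts 0/1/2, `NA` for missing calls) with sample
#' identifiers on the rows and variant metadata on the columns.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   every non-missing entry must be 0, 1 or 2.
#' @param variants optional `data.frame` with columns `chrom`, `pos` (0-based),
#'   `id`, `ref`, `alt`; defaults to the column names of `dosages` as ids with
#'   unknown coordinates.
#' @param samples optional character vector of sample identifiers; defaults to
#'   the row names of `dosages`.
#' @param validate check every dosage value (default `TRUE`). The built-in
#'   simulator disables this for its own draws, which are 0/1/2 by
#'   construction; data from outside sources should always be validated.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants`, `samples`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1, 0, 2), nrow = 3,
#'                             dimnames = list(c("a", "b", "c"), c("v1", "v2"))))
#' g
#' @export
genotype_matrix <- function(dosages, variants = NULL, samples = NULL,
                            validate = TRUE) {
  dosages <- as.matrix(dosages)
  if (validate) storage.mode(dosages) <- "double"
  n <- nrow(dosages); m <- ncol(dosages)
  if (n < 1 || m < 1)
    stop("a genotype matrix needs at least 1 sample and 1 variant", call. = FALSE)
  samples <- as.character(samples %||% rownames(dosages) %||%
                            paste0("sample_", seq_len(n)))
  if (length(samples) != n) stop("sample ids do not match row count", call. = FALSE)
  if (anyDuplicated(samples)) stop("sample identifiers must be unique", call. = FALSE)
  if (is.null(variants)) {
    ids <- colnames(dosages) %||% paste0("snp_", seq_len(m))
    variants <- data.frame(chrom = NA_character_, pos = NA_integer_,
                           id = as.character(ids), ref = NA_character_,
                           alt = NA_character_, stringsAsFactors = FALSE)
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "ref", "alt")
  for (cc in setdiff(need, names(variants))) variants[[cc]] <- NA
  variants <- variants[need]
  if (nrow(variants) != m) stop("variant table does not match column count", call. = FALSE)
  if (anyDuplicated(variants$id)) stop("variant identifiers must be unique", call. = FALSE)
  if (validate) {
    bad <- !is.na(dosages) & !(dosages == 0 | dosages == 1 | dosages == 2)
    if (any(bad))
      stop("dosages must be 0, 1, 2 or NA; first offending value: ",
           dosages[which(bad)[1]], call. = FALSE)
  }
  dimnames(dosages) <- list(samples, variants$id)
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants, %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

keep_variants <- function(g, keep) {
  if (!any(keep)) stop("no variants left", call. = FALSE)
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  variants = g$variants[keep, , drop = FALSE],
                  samples = g$samples)
}

gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  val <- vapply(u, function(s) {
    if (is.na(s) || s == ".") return(NA_real_)
    al <- strsplit(s, "[/|]", perl = FALSE)[[1]]
    if (length(al) == 0 || any(al == ".")) return(NA_real_)
    sum(al != "0")
  }, numeric(1))
  matrix(val[match(as.vector(gt), u)], nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Read genotypes from a VCF file
#'
#' Converts the GT fields of a VCF 4.x file into ALT-allele dosages. Missing
#' genotypes (`./.` or `.|.`) become `NA`, never 0. All positions are stored
#' 0-based internally (VCF is 1-based on disk).
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param biallelic_only drop multiallelic records and records whose REF or
#'   ALT is not a single nucleotide (default `TRUE`).
#' @return a [genotype_matrix()].
#' @examples
#' vcf <- system.file("extdata", "synthetic_toy.vcf", package = "trianet")
#' read_vcf(vcf)
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse VCF '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no usable variants in '", path, "'", call. = FALSE)
  keep <- rep(TRUE, nrow(fix))
  if (biallelic_only) {
    keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE) &
      nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
      fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  }
  if (!any(keep))
    stop("no usable variants in '", path,
         "' after biallelic SNP filtering", call. = FALSE)
  vcf <- vcf[keep, ]
  fix <- fix[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos <- t(gt_to_dosage(gt))                       # samples x variants
  pos1 <- as.integer(fix$POS)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, pos1, fix$REF, fix$ALT, sep = ":"), fix$ID)
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_dup")
  genotype_matrix(dos,
                  variants = data.frame(chrom = fix$CHROM, pos = pos1 - 1L,
                                        id = ids, ref = fix$REF, alt = fix$ALT,
                                        stringsAsFactors = FALSE),
                  samples = colnames(gt))
}

#' Write / read the plain delimited genotype-matrix format
#'
#' Tab-delimited text: first row sample identifiers, first column variant
#' identifiers (rows are variants), missing dosages coded `NA`. Writing and
#' re-reading reproduces dosages and identifiers exactly.
#'
#' @param g a [genotype_matrix()].
#' @param path output (input) file path.
#' @return `write_genotype_matrix()` returns `path` invisibly;
#'   `read_genotype_matrix()` returns a [genotype_matrix()] (variant
#'   coordinates are not carried by this format and come back as `NA`).
#' @export
write_genotype_matrix <- function(g, path) {
  tab <- t(g$dosages)
  out <- data.frame(id = g$variants$id, tab, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("id", g$samples)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("not a genotype-matrix file: ", path, call. = FALSE)
  ids <- as.character(tab[[1]])
  dos <- t(as.matrix(tab[, -1, drop = FALSE]))
  genotype_matrix(dos,
                  variants = data.frame(chrom = NA_character_, pos = NA_integer_,
                                        id = ids, ref = NA_character_,
                                        alt = NA_character_,
                                        stringsAsFactors = FALSE),
                  samples = colnames(tab)[-1])
}

#' Genomic region sets (BED convention)
#'
#' Intervals are 0-based half-open `[start, end)`, the BED convention; all
#' internal variant positions use the same 0-based system.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer interval bounds, `start < end`.
#' @return a `data.frame` of class `region_set`.
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer()) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("regions must satisfy start < end", call. = FALSE)
  structure(data.frame(chrom = as.character(chrom), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("region_set", "data.frame"))
}

#' Read a 3-column BED file of regions
#'
#' @param path BED file (chrom, start, end; extra columns ignored).
#' @return a [region_set()].
#' @export
read_bed_regions <- function(path) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns: ", path, call. = FALSE)
  region_set(tab[[1]], tab[[2]], tab[[3]])
}

minor_allele_freqs <- function(g) {
  calls <- colSums(!is.na(g$dosages))
  p <- colSums(g$dosages, na.rm = TRUE) / (2 * calls)
  pmin(p, 1 - p)
}

#' Filter variants by minor allele frequency
#'
#' Keeps exactly the variants whose MAF (computed on non-missing calls) is
#' *strictly* greater than `threshold`.
#'
#' @param g a [genotype_matrix()].
#' @param threshold frequency in `[0, 0.5)`; default 0.05.
#' @return filtered [genotype_matrix()].
#' @export
maf_filter <- function(g, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold < 0.5)
  keep <- minor_allele_freqs(g) > threshold
  if (!any(keep))
    stop("MAF filter removed every variant; consider a lower threshold",
         call. = FALSE)
  keep_variants(g, keep)
}

#' Greedy sliding-window linkage-disequilibrium pruning
#'
#' Within each window of `window` consecutive variants (advanced by `step`),
#' any pair of retained variants whose squared Pearson correlation of dosages
#' exceeds `r2_max` loses its later member. Output variant order is
#' preserved. A window larger than the panel is processed as a single window.
#'
#' @param g a [genotype_matrix()].
#' @param window window size in SNPs (>= 2).
#' @param step slide in SNPs.
#' @param r2_max squared-correlation threshold in `(0, 1]`.
#' @return pruned [genotype_matrix()].
#' @export
ld_prune <- function(g, window = 50, step = 5, r2_max = 0.2) {
  stopifnot(window >= 2, step >= 1, r2_max > 0, r2_max <= 1)
  m <- ncol(g$dosages)
  keep <- rep(TRUE, m)
  starts <- seq(1, max(1, m - 1), by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1, m)
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    cm <- suppressWarnings(cor(g$dosages[, idx, drop = FALSE],
                               use = "pairwise.complete.obs"))
    cm[is.na(cm)] <- 0
    for (a in seq_len(length(idx) - 1)) {
      if (!keep[idx[a]]) next
      for (b in (a + 1):length(idx)) {
        if (keep[idx[b]] && cm[a, b]^2 > r2_max) keep[idx[b]] <- FALSE
      }
    }
  }
  if (!any(keep))
    stop("LD pruning removed every variant", call. = FALSE)
  keep_variants(g, keep)
}

#' Exclude variants falling in a set of regions
#'
#' Removes variants whose (0-based) position lies in any interval of
#' `regions`, using the half-open BED convention: start inclusive, end
#' exclusive. An empty region set is the identity. Intended for the standard
#' long-range LD exclusion lists used before structure inference.
#'
#' @param g a [genotype_matrix()].
#' @param regions a [region_set()].
#' @return filtered [genotype_matrix()].
#' @export
exclude_regions <- function(g, regions) {
  if (nrow(regions) == 0) return(g)
  drop <- rep(FALSE, ncol(g$dosages))
  for (ch in unique(regions$chrom)) {
    rr <- regions[regions$chrom == ch, , drop = FALSE]
    on_ch <- which(!is.na(g$variants$chrom) & g$variants$chrom == ch)
    if (length(on_ch) == 0) next
    pos <- g$variants$pos[on_ch]
    hit <- vapply(pos, function(p) any(p >= rr$start & p < rr$end), logical(1))
    drop[on_ch[hit]] <- TRUE
  }
  if (all(drop)) stop("region exclusion removed every variant", call. = FALSE)
  keep_variants(g, !drop)
}
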