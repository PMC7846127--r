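# Readers and writers for plink BED/BIM/FAM, TSV genotype/relatedness
# matrices, subpopulation labels and weight vectors. All text formats are
# tab-separated with a header; relatedness matrices carry their form in a
# leading comment line.

#' Read genotypes from plink BED/BIM/FAM or TSV
#'
#' For `format = "bed"`, `path` is the file-set prefix (or the `.bed` path);
#' the BIM and FAM files must sit alongside. The BED file must be in
#' SNP-major (variant-major) mode, magic bytes `0x6c 0x1b 0x01`; dosages
#' count copies of the BIM allele-1, and the missing code surfaces as `NA`.
#' For `format = "tsv"`, the file has a header of individual IDs and a
#' first column of locus IDs.
#'
#' Estimators reject matrices containing `NA`; set
#' `drop_missing_loci = TRUE` to remove loci with any missing genotype at
#' read time (the count removed is reported), an explicit complete-loci
#' extension of the complete-data estimators.
#'
#' @param path File prefix (bed) or file path (tsv).
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @param drop_missing_loci Drop loci containing missing genotypes.
#' @return List with `X` (loci x n dosage matrix with dimnames), and for
#'   plink input the `bim` and `fam` tables.
#' @export
read_genotypes <- function(path, format = c("auto", "bed", "tsv"),
                           drop_missing_loci = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tsv$", path)) "tsv" else "bed"
  out <- if (format == "bed") read_plink(path) else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    X <- as.matrix(tab[, -1, drop = FALSE])
    rownames(X) <- tab[[1]]
    storage.mode(X) <- "integer"
    list(X = X)
  }
  if (anyNA(out$X) && drop_missing_loci) {
    bad <- rowSums(is.na(out$X)) > 0
    message("read_genotypes: dropping ", sum(bad), " loci with missing genotypes")
    out$X <- out$X[!bad, , drop = FALSE]
    if (!is.null(out$bim)) out$bim <- out$bim[!bad, , drop = FALSE]
  }
  out
}

plink_paths <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  list(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
       fam = paste0(prefix, ".fam"))
}

read_plink <- function(prefix) {
  pp <- plink_paths(prefix)
  fam <- utils::read.table(pp$fam, header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  bim <- utils::read.table(pp$bim, header = FALSE,
                           col.names = c("chr", "id", "cm", "pos", "a1", "a2"))
  n <- nrow(fam)
  m <- nrow(bim)
  bpv <- ceiling(n / 4)
  raw <- readBin(pp$bed, "raw", n = 3 + bpv * m)
  if (length(raw) < 3 ||
      !identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major plink BED file (bad magic bytes): ", pp$bed)
  if (length(raw) < 3 + bpv * m) stop("BED file truncated: ", pp$bed)
  bytes <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
  # 2-bit codes, sample slots from the low bits: 00=2 copies of a1,
  # 01=missing, 10=het, 11=0 copies
  dosage_of_code <- c(2L, NA_integer_, 1L, 0L)
  X <- matrix(NA_integer_, m, n)
  for (k in 1:4) {
    if (k > n) break
    cols <- seq.int(k, n, by = 4L)
    codes <- bytes[seq_along(cols), , drop = FALSE] %/% 4L^(k - 1) %% 4L
    X[, cols] <- t(matrix(dosage_of_code[codes + 1L], nrow = length(cols)))
  }
  dimnames(X) <- list(bim$id, fam$iid)
  list(X = X, bim = bim, fam = fam)
}

#' Write genotypes as a plink BED/BIM/FAM file set
#'
#' Writes SNP-major BED (magic `0x6c 0x1b 0x01`) with dosages counting
#' allele-1 and `NA` encoded as the missing code, plus minimal BIM
#' (chromosome 1, positions = locus index, alleles A/B) and FAM tables.
#'
#' @param prefix Output file-set prefix.
#' @param X Loci x n dosage matrix (`{0,1,2}` or `NA`).
#' @param locus_ids,ind_ids Optional IDs (default from dimnames or
#'   generated).
#' @return The prefix, invisibly.
#' @export
write_plink <- function(prefix, X, locus_ids = NULL, ind_ids = NULL) {
  m <- nrow(X); n <- ncol(X)
  if (is.null(locus_ids))
    locus_ids <- if (!is.null(rownames(X))) rownames(X) else paste0("snp", seq_len(m))
  if (is.null(ind_ids))
    ind_ids <- if (!is.null(colnames(X))) colnames(X) else paste0("ind", seq_len(n))
  pp <- plink_paths(prefix)
  # dosage -> 2-bit code: 2 -> 00, het -> 10, 0 -> 11, NA -> 01
  code_of_dosage <- c(3L, 2L, 0L)
  cd <- matrix(1L, 4L * ceiling(n / 4), m) # pre-fill with missing
  cd[seq_len(n), ] <- {
    v <- code_of_dosage[t(X) + 1L]
    v[is.na(v)] <- 1L
    matrix(v, n, m)
  }
  cd[seq.int(n + 1L, length.out = nrow(cd) - n), ] <- 0L # pad bits are zero
  dim(cd) <- c(4L, length(cd) / 4L)
  bytes <- as.raw(colSums(cd * c(1L, 4L, 16L, 64L)))
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), bytes), pp$bed)
  utils::write.table(
    data.frame(1, locus_ids, 0, seq_len(m), "A", "B"),
    pp$bim, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(ind_ids, ind_ids, 0, 0, 0, -9),
    pp$fam, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Write genotypes as TSV
#'
#' Header of individual IDs, first column (`id`) of locus IDs.
#'
#' @param path Output path.
#' @inheritParams write_plink
#' @return The path, invisibly.
#' @export
write_genotypes_tsv <- function(path, X, locus_ids = NULL, ind_ids = NULL) {
  if (is.null(locus_ids))
    locus_ids <- if (!is.null(rownames(X))) rownames(X) else paste0("snp", seq_len(nrow(X)))
  if (is.null(ind_ids))
    ind_ids <- if (!is.null(colnames(X))) colnames(X) else paste0("ind", seq_len(ncol(X)))
  tab <- data.frame(id = locus_ids, X, check.names = FALSE)
  colnames(tab) <- c("id", ind_ids)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a relatedness matrix as TSV
#'
#' The file starts with a metadata comment line `# form=<form>
#' reference=<label>`, followed by a header row of individual IDs and one
#' row per individual (ID in the first column).
#'
#' @param M A [relatedness_matrix()].
#' @param path File path.
#' @return `write_relatedness()` returns the path invisibly;
#'   `read_relatedness()` returns the relatedness matrix.
#' @export
write_relatedness <- function(M, path) {
  form <- rel_form(M)
  ids <- if (!is.null(colnames(M))) colnames(M) else paste0("ind", seq_len(ncol(M)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# form=%s reference=%s", form,
                     attr(M, "reference") %||% "MRCA"), con)
  writeLines(paste(c("id", ids), collapse = "\t"), con)
  utils::write.table(data.frame(id = ids, unclass(M), check.names = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_relatedness
#' @export
read_relatedness <- function(path) {
  first <- readLines(path, n = 1)
  form <- sub(".*form=([a-z]+).*", "\\1", first)
  reference <- if (grepl("reference=", first))
    sub(".*reference=(.*)$", "\\1", first) else "MRCA"
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                           check.names = FALSE)
  M <- as.matrix(tab[, -1, drop = FALSE])
  rownames(M) <- tab[[1]]
  relatedness_matrix(M, form = form, reference = reference)
}

#' Read subpopulation labels
#'
#' TSV with header and columns `id`, `label`. IDs must be unique; when
#' `ids` is given the labels are reordered to match and every ID must be
#' present.
#'
#' @param path File path.
#' @param ids Optional individual IDs to align to.
#' @return Named vector of labels.
#' @export
read_labels <- function(path, ids = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (anyDuplicated(tab$id)) stop("duplicate individual IDs in ", path)
  lab <- stats::setNames(tab$label, tab$id)
  if (!is.null(ids)) {
    miss <- setdiff(ids, names(lab))
    if (length(miss)) stop("labels missing for IDs: ", paste(miss, collapse = ", "))
    lab <- lab[ids]
  }
  lab
}

#' Read a weight vector
#'
#' TSV with header and columns `id`, `weight`. Negative weights are an
#' error; weights not summing to one (beyond 1e-6) are renormalized with a
#' warning.
#'
#' @inheritParams read_labels
#' @return Named numeric weight vector summing to one.
#' @export
read_weights <- function(path, ids = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (anyDuplicated(tab$id)) stop("duplicate individual IDs in ", path)
  w <- stats::setNames(as.numeric(tab$weight), tab$id)
  if (any(w < 0)) stop("negative weights in ", path)
  if (abs(sum(w) - 1) > 1e-6) {
    warning("weights sum to ", signif(sum(w), 6), "; renormalizing to 1")
  }
  w <- w / sum(w)
  if (!is.null(ids)) {
    miss <- setdiff(ids, names(w))
    if (length(miss)) stop("weights missing for IDs: ", paste(miss, collapse = ", "))
    w <- w[ids]
  }
  w
}
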