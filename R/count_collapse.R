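# Collapse per-variant gene counts (base, "-iso", "-ext<x>kb") in a sparse
# cells x gene-variant matrix into final per-gene counts. Suffix matching is
# end-anchored and restricted to x in 1..10, so natural gene symbols cannot
# be stripped by accident; "-ext<x>kb" is stripped before "-iso" (the
# suffixes stack in iso-then-ext order).

EXT_RE <- "-ext([1-9]|10)kb$"
ISO_RE <- "-iso$"

#' Parse gene-variant identifiers into keys
#'
#' A terminal `-ext<x>kb` (x an integer 1-10) is stripped first, then a
#' terminal `-iso`; the remainder is the base gene identifier. Strings
#' matching neither suffix are `variant = "base"` and never fail to parse.
#'
#' @param raw Character vector of matrix column identifiers.
#' @return A `data.table` with columns `raw`, `base`, `variant` (one of
#'   `"base"`, `"iso"`, `"ext"`) and `ext_step` (integer 1-10, NA unless
#'   `variant == "ext"`).
#' @examples
#' parse_gene_key(c("SOX9", "G1-iso", "G1-iso-ext10kb"))
#' @export
parse_gene_key <- function(raw) {
  stopifnot(is.character(raw), all(nzchar(raw)))
  has_ext <- grepl(EXT_RE, raw)
  step <- rep(NA_integer_, length(raw))
  stripped <- raw
  if (any(has_ext)) {
    step[has_ext] <- as.integer(sub(paste0("^.*", EXT_RE), "\\1", raw[has_ext]))
    stripped[has_ext] <- sub(EXT_RE, "", raw[has_ext])
  }
  has_iso <- grepl(ISO_RE, stripped)
  stripped[has_iso] <- sub(ISO_RE, "", stripped[has_iso])
  variant <- fifelse(has_ext, "ext", fifelse(has_iso, "iso", "base"))
  data.table(raw = raw, base = stripped, variant = variant, ext_step = step)
}

#' Reconstruct the raw identifier of a gene key
#'
#' Inverse of [parse_gene_key()] for keys it produced.
#'
#' @param key A `data.table` as returned by [parse_gene_key()].
#' @return Character vector of raw identifiers.
#' @export
format_gene_key <- function(key) {
  out <- key$base
  # ext variants produced by this tool ride on an -iso gene only when the
  # raw id said so; reconstruct from raw where available
  iso <- key$variant == "iso"
  out[iso] <- paste0(out[iso], "-iso")
  ext <- key$variant == "ext"
  if (any(ext)) {
    mid <- sub(EXT_RE, "", key$raw[ext])
    out[ext] <- paste0(mid, "-ext", key$ext_step[ext], "kb")
  }
  out
}

#' Construct a cells x gene-variant count matrix
#'
#' @param values A sparse non-negative matrix (cells in rows, gene variants
#'   in columns); coerced to `dgCMatrix`.
#' @param cell_ids Character vector of barcodes (row names).
#' @param gene_ids Character vector of column identifiers (may carry
#'   `-iso` / `-ext<x>kb` suffixes).
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(values, cell_ids, gene_ids) {
  values <- methods::as(methods::as(values, "CsparseMatrix"), "dMatrix")
  if (nrow(values) != length(cell_ids))
    stop("nrow(values) != length(cell_ids)")
  if (ncol(values) != length(gene_ids))
    stop("ncol(values) != length(gene_ids)")
  if (length(values@x) && any(values@x < 0))
    stop("negative counts are not allowed")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = as.character(cell_ids),
                 gene_keys = parse_gene_key(as.character(gene_ids))),
            class = "CountMatrix")
}

#' @exportS3Method base::print
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cell(s) x %d gene column(s), total count %s\n",
              nrow(x$values), ncol(x$values),
              format(sum(x$values), scientific = FALSE)))
  tab <- table(x$gene_keys$variant)
  cat("  variants:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Collapse gene-variant columns to per-gene totals
#'
#' Output columns are the distinct base identifiers in order of first
#' appearance; each entry is the sum over all input columns sharing that
#' base. Cell order is preserved and the total count of every cell (hence
#' the grand total) is conserved. Collapsing an already-collapsed matrix is
#' a no-op.
#'
#' If an input column equals another column's stripped base (e.g. both `G1`
#' and `G1-iso` present), the two are summed together and a warning is
#' emitted, since a properly augmented annotation renames the base gene.
#'
#' @param m A [count_matrix()].
#' @return A collapsed [count_matrix()] whose columns are base genes.
#' @export
collapse_counts <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  keys <- m$gene_keys
  if (!nrow(keys)) return(m)
  # a base column next to an -iso-renamed variant means the matrix mixes
  # identifiers from before and after augmentation; an unsuffixed base next
  # to its own -ext<x>kb column is the method's normal case
  iso_bearing <- grepl(ISO_RE, sub(EXT_RE, "", keys$raw))
  mixed <- keys[, .(has_base = any(variant == "base"),
                    has_iso = any(iso_bearing[.I])), by = base]
  n_mixed <- sum(mixed$has_base & mixed$has_iso)
  if (n_mixed)
    warning(n_mixed, " base gene(s) present both unsuffixed and in an ",
            "-iso-renamed variant; their counts are summed together")
  ubase <- unique(keys$base)
  j <- match(keys$base, ubase)
  ind <- sparseMatrix(i = seq_along(j), j = j, x = 1,
                      dims = c(length(j), length(ubase)))
  vals <- m$values %*% ind
  count_matrix(vals, m$cell_ids, ubase)
}

#' Read a CellRanger-style Matrix Market triplet
#'
#' Expects `matrix.mtx` (genes x cells, as written by CellRanger),
#' `features.tsv` or `genes.tsv` (column 1 = gene identifier) and
#' `barcodes.tsv` in one directory; the matrix is transposed to cells x
#' genes on read.
#'
#' @param dir Directory containing the triplet.
#' @param id_col Which features column to use as identifier (default 1).
#' @return A [count_matrix()].
#' @export
read_matrix_triplet <- function(dir, id_col = 1L) {
  mtx <- file.path(dir, "matrix.mtx")
  feats <- file.path(dir, "features.tsv")
  if (!file.exists(feats)) feats <- file.path(dir, "genes.tsv")
  bcs <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feats, bcs))
    if (!file.exists(f)) stop("missing triplet file: ", f)
  m <- readMM(mtx)
  read_tsv_or_empty <- function(f) {
    if (file.size(f) == 0) data.table(V1 = character())
    else fread(f, header = FALSE, sep = "\t")
  }
  ft <- read_tsv_or_empty(feats)
  bc <- read_tsv_or_empty(bcs)
  if (nrow(ft) != nrow(m))
    stop("features table has ", nrow(ft), " row(s) but matrix has ",
         nrow(m), " row(s)")
  if (nrow(bc) != ncol(m))
    stop("barcodes table has ", nrow(bc), " row(s) but matrix has ",
         ncol(m), " column(s)")
  count_matrix(Matrix::t(m), bc[[1L]], ft[[id_col]])
}

#' Write a CellRanger-style Matrix Market triplet
#'
#' Writes `matrix.mtx` (genes x cells), `features.tsv` (identifier and
#' name columns) and `barcodes.tsv`. Output is deterministic.
#'
#' @param m A [count_matrix()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_matrix_triplet <- function(m, dir) {
  stopifnot(inherits(m, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMM(Matrix::t(m$values), file.path(dir, "matrix.mtx"))
  fwrite(data.table(id = m$gene_keys$raw, name = m$gene_keys$raw),
         file.path(dir, "features.tsv"), sep = "\t", col.names = FALSE,
         quote = FALSE)
  fwrite(data.table(bc = m$cell_ids), file.path(dir, "barcodes.tsv"),
         sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write a dense TSV view of a count matrix (toy inputs)
#'
#' @param m A [count_matrix()].
#' @param path Output TSV path (cells in rows).
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(m, path) {
  dt <- as.data.table(as.matrix(m$values))
  setnames(dt, m$gene_keys$raw)
  dt <- cbind(data.table(barcode = m$cell_ids), dt)
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
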