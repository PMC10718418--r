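# Sparse local and global IBD matrices.
#
# A local matrix holds, for one genomic window, the number of genome copies
# (0..2) each pair of individuals shares IBD, averaged over the window:
# entry(i,j) = sum over the <=4 haplotype pairs of
#              (length of the union of that pair's segments within the
#               window) / (window width).
# The diagonal is zero by construction (self-sharing excluded).  The global
# matrix is the window-width-weighted genome average of the local matrices
# plus 2 on the diagonal, and doubles as the kinship-style covariance of the
# polygenic random effect.

#' Local IBD matrix
#'
#' Sparse symmetric N x N matrix of pairwise IBD sharing (genome copies in
#' [0, 2]) within one genomic window, with a zero diagonal.
#'
#' @slot window_id integer window identifier (0-based, genome-ordered).
#' @slot width_cM window width in cM.
#' @slot nnz_offdiag number of non-zero off-diagonal elements (both
#'   triangles).
#' @slot sample_ids sample IDs defining row/column order.
#' @export
setClass("local_ibd", contains = "dsCMatrix",
         slots = c(window_id = "integer", width_cM = "numeric",
                   nnz_offdiag = "integer", sample_ids = "character"))

#' Global IBD matrix
#'
#' Sparse symmetric N x N genome-average IBD sharing with diagonal 2,
#' optionally thresholded to a block-diagonal (under symmetric permutation)
#' pattern.
#'
#' @slot sample_ids sample IDs defining row/column order.
#' @slot threshold off-diagonal threshold that was applied (0 if none).
#' @slot blocks integer membership vector of connected components.
#' @slot block_sizes sizes of the components.
#' @slot largest_block size of the largest component.
#' @slot perm permutation ordering samples by block.
#' @export
setClass("global_ibd", contains = "dsCMatrix",
         slots = c(sample_ids = "character", threshold = "numeric",
                   blocks = "integer", block_sizes = "integer",
                   largest_block = "integer", perm = "integer"))

.as_dsc <- function(m)
  as(as(as(forceSymmetric(m), "CsparseMatrix"), "symmetricMatrix"),
     "dsCMatrix")

# Interval-union overlap per haplotype-pair group, fully vectorized.
# s, e already clipped to the window.  Classic sorted sweep: within each
# group sorted by start, a piece contributes
# max(0, end - max(start, running max of previous ends)).
.union_lengths <- function(g, s, e) {
  o <- order(g, s, e)
  g <- g[o]; s <- s[o]; e <- e[o]
  cm <- ave(e, g, FUN = cummax)
  prev <- ave(cm, g, FUN = function(x) c(-Inf, x[-length(x)]))
  contrib <- pmax(0, e - pmax(s, prev))
  rowsum(contrib, g, reorder = FALSE)
}

#' Build the local IBD matrix for one window
#'
#' For each canonical haplotype pair, overlapping or duplicate segment calls
#' are unioned before the overlap with the window is measured, so redundant
#' caller output cannot inflate sharing; individual-pair entries are the sum
#' over the pair's haplotype pairs and are clipped to 2 copies.
#'
#' @param seg an \code{ibd_segments} table.
#' @param window a one-row data frame (or list) with \code{chrom},
#'   \code{start_cM}, \code{end_cM}, \code{window_id}.
#' @param sample_ids character vector of the N sample IDs defining row and
#'   column order; segments involving unknown IDs are an error.
#' @return a [local_ibd-class] sparse symmetric matrix.
#' @export
build_local_matrix <- function(seg, window, sample_ids) {
  w0 <- as.numeric(window$start_cM); w1 <- as.numeric(window$end_cM)
  width <- w1 - w0
  if (!is.finite(width) || width <= 0) stop("window width must be positive")
  N <- length(sample_ids)
  keep <- seg$chrom == as.character(window$chrom) &
    seg$start_cM < w1 & seg$end_cM > w0
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg) == 0L)
    return(.local_ibd(sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(N, N),
                                   symmetric = TRUE),
                      window$window_id, width, sample_ids))
  i1 <- match(seg$id1, sample_ids); i2 <- match(seg$id2, sample_ids)
  if (anyNA(i1) || anyNA(i2))
    stop("segment sample IDs absent from sample_ids: ",
         paste(head(unique(c(seg$id1[is.na(i1)], seg$id2[is.na(i2)])), 5L),
               collapse = ", "))
  s <- pmax(seg$start_cM, w0); e <- pmin(seg$end_cM, w1)
  # union per haplotype pair first, then aggregate to the individual pair
  gkey <- paste(i1, seg$hap1, i2, seg$hap2, sep = "\r")
  ul <- .union_lengths(gkey, s, e)
  parts <- matrix(as.numeric(unlist(strsplit(rownames(ul), "\r",
                                             fixed = TRUE))),
                  ncol = 4L, byrow = TRUE)
  pkey <- paste(parts[, 1L], parts[, 3L], sep = "\r")
  pv <- rowsum(ul[, 1L] / width, pkey, reorder = FALSE)
  pl <- matrix(as.numeric(unlist(strsplit(rownames(pv), "\r", fixed = TRUE))),
               ncol = 2L, byrow = TRUE)
  x <- pmin(pv[, 1L], 2)
  ii <- pmin(pl[, 1L], pl[, 2L]); jj <- pmax(pl[, 1L], pl[, 2L])
  m <- sparseMatrix(i = ii, j = jj, x = x, dims = c(N, N), symmetric = TRUE)
  .local_ibd(m, window$window_id, width, sample_ids)
}

.local_ibd <- function(m, window_id, width, sample_ids) {
  m <- drop0(.as_dsc(m))
  new("local_ibd", m, window_id = as.integer(window_id),
      width_cM = as.numeric(width),
      nnz_offdiag = 2L * (length(m@x) - sum(diag(m) != 0)),
      sample_ids = as.character(sample_ids %||% character(0)))
}

#' Number of non-zero off-diagonal elements
#' @param m a [local_ibd-class] matrix.
#' @return integer count (both triangles).
#' @export
nnz_offdiag <- function(m) m@nnz_offdiag

#' Build local IBD matrices for every window of a grid
#'
#' @param seg an \code{ibd_segments} table.
#' @param grid a [make_window_grid()] result.
#' @param sample_ids sample ID vector defining matrix order.
#' @return a list of [local_ibd-class] matrices in grid order.
#' @export
build_local_matrices <- function(seg, grid, sample_ids) {
  lapply(seq_len(nrow(grid)),
         function(i) build_local_matrix(seg, grid[i, ], sample_ids))
}

#' Build the global IBD matrix
#'
#' The genome-wide average of the local IBD matrices, weighted by window
#' width so that the truncated last window of each chromosome does not
#' distort the average, plus 2 on the diagonal (each non-inbred individual
#' shares two copies of the genome with themselves).
#'
#' @param locals list of [local_ibd-class] matrices covering the genome.
#' @param threshold optional off-diagonal threshold applied immediately
#'   (see [sparsify_global()]); \code{NULL} keeps all entries.
#' @return a [global_ibd-class] sparse symmetric matrix.
#' @export
build_global_matrix <- function(locals, threshold = NULL) {
  stopifnot(length(locals) > 0L)
  Ns <- vapply(locals, nrow, integer(1))
  if (length(unique(Ns)) != 1L) stop("local matrices differ in N")
  ws <- vapply(locals, function(m) m@width_cM, numeric(1))
  acc <- as(locals[[1L]], "dsCMatrix") * ws[1L]
  for (k in seq_along(locals)[-1L])
    acc <- acc + as(locals[[k]], "dsCMatrix") * ws[k]
  phi <- .as_dsc(acc / sum(ws))
  diag(phi) <- 2
  g <- .add_blocks(new("global_ibd", drop0(phi),
                       sample_ids = locals[[1L]]@sample_ids,
                       threshold = 0))
  if (!is.null(threshold)) g <- sparsify_global(g, threshold)
  g
}

#' Wrap a sparse symmetric matrix as a global IBD matrix
#'
#' Convenience constructor used when the kinship-style matrix comes from
#' elsewhere (e.g. \code{2 * Diagonal(N)} for unrelated samples).
#'
#' @param m sparse symmetric matrix with diagonal 2.
#' @param sample_ids optional sample IDs (defaults to \code{"S1"..."SN"}).
#' @return a [global_ibd-class] object.
#' @export
global_ibd <- function(m, sample_ids = NULL) {
  m <- drop0(.as_dsc(m))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(m)))
  .add_blocks(new("global_ibd", m, sample_ids = as.character(sample_ids),
                  threshold = 0))
}

#' Threshold the global IBD matrix to a sparse block-diagonal form
#'
#' Off-diagonal entries strictly below \code{threshold} are set to zero.
#' The default 0.088 keeps fourth-degree relatives or closer (kinship
#' coefficient >= 0.022 on the 0..2 genome-copies scale).  Connected
#' components of the retained off-diagonal pattern define blocks over which
#' a symmetric permutation makes the matrix block-diagonal.
#'
#' @param phi a [global_ibd-class] object (or sparse symmetric matrix).
#' @param threshold non-negative cutoff (default 0.088).
#' @return a [global_ibd-class] with updated block structure.
#' @export
sparsify_global <- function(phi, threshold = 0.088) {
  stopifnot(threshold >= 0)
  ids <- if (is(phi, "global_ibd")) phi@sample_ids
         else paste0("S", seq_len(nrow(phi)))
  m <- .as_dsc(phi)
  if (threshold > 0) {
    tri <- as(m, "TsparseMatrix")
    drop <- tri@i != tri@j & abs(tri@x) < threshold
    tri@x[drop] <- 0
    m <- drop0(.as_dsc(tri))
  }
  .add_blocks(new("global_ibd", m, sample_ids = ids,
                  threshold = as.numeric(threshold)))
}

# connected components of the off-diagonal sparsity pattern (union-find
# with path halving)
.add_blocks <- function(g) {
  N <- nrow(g)
  tri <- as(as(g, "generalMatrix"), "TsparseMatrix")
  off <- tri@i < tri@j
  parent <- seq_len(N)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  ii <- tri@i[off] + 1L; jj <- tri@j[off] + 1L
  for (k in seq_along(ii)) {
    ra <- find(ii[k]); rb <- find(jj[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(N), find, integer(1))
  memb <- match(roots, unique(roots))
  sizes <- tabulate(memb)
  g@blocks <- memb
  g@block_sizes <- sizes
  g@largest_block <- if (length(sizes)) max(sizes) else 0L
  g@perm <- order(memb)
  g
}

#' @export
setMethod("show", "global_ibd", function(object) {
  cat(sprintf(paste0("Global IBD matrix: N = %d, %d non-zero off-diagonal",
                     " entries\n  threshold %.3f, %d block(s),",
                     " largest block %d\n"),
              nrow(object),
              2L * (length(object@x) - sum(diag(object) != 0)),
              object@threshold, length(object@block_sizes),
              object@largest_block))
  invisible(object)
})

#' @export
setMethod("show", "local_ibd", function(object) {
  cat(sprintf("Local IBD matrix: window %d (%.3g cM), N = %d, nnz = %d\n",
              object@window_id, object@width_cM, nrow(object),
              object@nnz_offdiag))
  invisible(object)
})

#' Persist / reload a local IBD matrix
#'
#' Matrices are written as MatrixMarket coordinate files (one triangle of
#' the symmetric pattern) with a JSON sidecar recording N, the window id and
#' width, so cached matrix sets can be re-scanned without rebuilding.
#'
#' @param m a [local_ibd-class] matrix.
#' @param path output path (\code{.mtx}; the sidecar appends \code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_local_matrix <- function(m, path) {
  Matrix::writeMM(as(m, "dsCMatrix"), path)
  meta <- sprintf(
    '{"N": %d, "window_id": %d, "width_cM": %.10g, "nnz_offdiag": %d}',
    nrow(m), m@window_id, m@width_cM, m@nnz_offdiag)
  writeLines(meta, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_local_matrix
#' @param path path of a matrix written by [write_local_matrix()].
#' @param sample_ids sample IDs to re-attach on read.
#' @export
read_local_matrix <- function(path, sample_ids = NULL) {
  m <- Matrix::readMM(path)
  meta <- paste(readLines(paste0(path, ".json")), collapse = "")
  num <- function(key)
    as.numeric(sub(paste0(".*\"", key, "\": *([-0-9.eE+]+).*"), "\\1", meta))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(m)))
  .local_ibd(m, num("window_id"), num("width_cM"), sample_ids)
}
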