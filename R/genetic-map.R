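#' Read a genetic map
#'
#' Reads a recombination map giving the genetic (cM) coordinate of physical
#' (bp) positions along each chromosome.  Two layouts are accepted: a
#' 3-column table \code{chrom, bp, cM} (header optional) and the PLINK-style
#' 4-column \code{chrom, snp_id, cM, bp}.  Within each chromosome the cM
#' coordinate must be non-decreasing in bp.
#'
#' @param path path to a whitespace/tab-delimited text file.
#' @param format \code{"auto"} (default, decided by column count),
#'   \code{"three"} or \code{"plink"}.
#' @return an object of class \code{genetic_map}: a list with one element per
#'   chromosome, each a data frame with columns \code{bp} and \code{cM},
#'   sorted by bp.
#' @seealso [bp_to_cm()], [make_window_grid()]
#' @export
read_genetic_map <- function(path, format = c("auto", "three", "plink")) {
  format <- match.arg(format)
  first <- readLines(path, n = 1L)
  fields <- strsplit(trimws(first), "[\t ]+")[[1]]
  ncol1 <- length(fields)
  # header detection: bp field must be numeric in a data row
  has_header <- is.na(suppressWarnings(as.numeric(fields[2L]))) &&
    is.na(suppressWarnings(as.numeric(fields[min(ncol1, 4L)])))
  tab <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (format == "auto") format <- if (ncol(tab) >= 4L) "plink" else "three"
  if (format == "plink") {
    if (ncol(tab) < 4L) stop("PLINK map format requires 4 columns")
    df <- data.frame(chrom = as.character(tab[[1L]]),
                     bp = as.numeric(tab[[4L]]),
                     cM = as.numeric(tab[[3L]]),
                     stringsAsFactors = FALSE)
  } else {
    if (ncol(tab) < 3L) stop("genetic map requires 3 columns (chrom, bp, cM)")
    df <- data.frame(chrom = as.character(tab[[1L]]),
                     bp = as.numeric(tab[[2L]]),
                     cM = as.numeric(tab[[3L]]),
                     stringsAsFactors = FALSE)
  }
  if (anyNA(df$bp) || anyNA(df$cM)) stop("non-numeric bp/cM values in map")
  genetic_map(df)
}

#' Construct a genetic map from a data frame
#'
#' @param df data frame with columns \code{chrom}, \code{bp}, \code{cM}.
#' @return a \code{genetic_map} object.
#' @export
genetic_map <- function(df) {
  stopifnot(all(c("chrom", "bp", "cM") %in% names(df)))
  out <- lapply(split(df[c("bp", "cM")], df$chrom), function(tab) {
    tab <- tab[order(tab$bp), , drop = FALSE]
    d <- diff(tab$cM)
    if (length(d) && any(d < 0)) {
      bad <- which(d < 0)[1L] + 1L
      stop(sprintf("cM decreases at bp %g (map row %d within chromosome)",
                   tab$bp[bad], bad))
    }
    rownames(tab) <- NULL
    tab
  })
  structure(out, class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  spans <- vapply(x, function(t) diff(range(t$cM)), numeric(1))
  cat(sprintf("Genetic map: %d chromosome(s), %.1f cM total\n",
              length(x), sum(spans)))
  for (ch in names(x))
    cat(sprintf("  %s: %d points, %.3f-%.3f cM\n", ch, nrow(x[[ch]]),
                min(x[[ch]]$cM), max(x[[ch]]$cM)))
  invisible(x)
}

#' Interpolate physical to genetic coordinates
#'
#' Linear interpolation of bp positions onto the cM scale of a genetic map.
#' Positions outside the mapped range of their chromosome are an error.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome identifier (scalar or vector recycled against
#'   \code{bp}).
#' @param bp physical positions (numeric vector).
#' @return numeric vector of cM positions.
#' @export
bp_to_cm <- function(map, chrom, bp) {
  stopifnot(inherits(map, "genetic_map"))
  n <- max(length(chrom), length(bp))
  chrom <- rep_len(as.character(chrom), n)
  bp <- rep_len(as.numeric(bp), n)
  out <- numeric(n)
  for (ch in unique(chrom)) {
    tab <- map[[ch]]
    if (is.null(tab)) stop("chromosome not in map: ", ch)
    idx <- which(chrom == ch)
    b <- bp[idx]
    if (any(b < min(tab$bp) - 1e-9) || any(b > max(tab$bp) + 1e-9))
      stop(sprintf("bp position outside mapped range on %s: [%g, %g]",
                   ch, min(tab$bp), max(tab$bp)))
    # ties = "ordered" average would break flat segments; approx handles
    # duplicated bp via ties = mean which is what we want on flat cM runs
    out[idx] <- approx(tab$bp, tab$cM, xout = b, ties = "ordered",
                       rule = 1)$y
  }
  out
}

#' Chunk a genetic map into windows
#'
#' Partitions each chromosome's cM span into contiguous half-open windows
#' \code{[start, start + w)} of width \code{width_cM}, anchored at the
#' chromosome's minimum mapped cM position.  The last window per chromosome
#' is truncated at the chromosome's maximum cM, so it may be shorter.
#'
#' @param map a [genetic_map()], or a data frame with columns \code{chrom},
#'   \code{start_cM}, \code{end_cM} giving each chromosome's span directly.
#' @param width_cM window width in cM (default 1).
#' @return a data frame of class \code{window_grid} with columns
#'   \code{window_id} (0-based, genome-ordered), \code{chrom},
#'   \code{start_cM}, \code{end_cM}.
#' @export
make_window_grid <- function(map, width_cM = 1) {
  stopifnot(width_cM > 0)
  if (inherits(map, "genetic_map")) {
    if (length(map) == 0L) stop("empty genetic map")
    spans <- data.frame(
      chrom = names(map),
      start_cM = vapply(map, function(t) min(t$cM), numeric(1)),
      end_cM = vapply(map, function(t) max(t$cM), numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    spans <- as.data.frame(map)
    stopifnot(all(c("chrom", "start_cM", "end_cM") %in% names(spans)))
    if (nrow(spans) == 0L) stop("empty genetic map")
  }
  pieces <- lapply(seq_len(nrow(spans)), function(i) {
    s <- spans$start_cM[i]; e <- spans$end_cM[i]
    span <- e - s
    if (span <= 0) return(NULL)
    k <- ceiling(span / width_cM - 1e-12)
    starts <- s + width_cM * (seq_len(k) - 1L)
    ends <- pmin(starts + width_cM, e)
    data.frame(chrom = spans$chrom[i], start_cM = starts, end_cM = ends,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  if (is.null(grid) || nrow(grid) == 0L) stop("genetic map spans zero cM")
  grid <- cbind(window_id = seq_len(nrow(grid)) - 1L, grid)
  rownames(grid) <- NULL
  class(grid) <- c("window_grid", "data.frame")
  grid
}
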