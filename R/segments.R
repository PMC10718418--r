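#' Read IBD segment calls
#'
#' Reads pairwise IBD-segment calls into a canonical segment table.  Three
#' dialects are supported:
#' \describe{
#'   \item{\code{generic}}{the package's own TSV: columns \code{id1, hap1,
#'     id2, hap2, chrom, start_bp, end_bp, start_cM, end_cM} with a header;
#'     the bp or the cM pair may be absent (cM is interpolated from
#'     \code{map} when missing).}
#'   \item{\code{hap-ibd}}{headerless 8 columns \code{id1, hap, id2, hap,
#'     chrom, start_bp, end_bp, length_cM}; haplotype indices 1/2 are
#'     recoded to 0/1 and cM endpoints are interpolated from \code{map}
#'     (required).}
#'   \item{\code{rapid}}{headerless 9 columns \code{chrom, id1, id2, hap1,
#'     hap2, start_bp, end_bp, start_cM, end_cM}.  Sample fields of the form
#'     \code{"ID<sep>hap"} are split on \code{hap_sep}.}
#' }
#' A custom layout can be supplied through \code{cols}, a named integer
#' vector mapping canonical names to column positions.
#'
#' Records failing validation (self pairs, non-positive length, unparseable
#' coordinates) are dropped; counts are attached as the \code{"rejected"}
#' attribute and reported via a message.  The haplotype pair
#' \code{(id1, hap1)-(id2, hap2)} is canonicalized with the lexicographically
#' smaller \code{(id, hap)} first so that duplicates are detectable.
#'
#' @param path file path.
#' @param dialect one of \code{"generic"}, \code{"hap-ibd"}, \code{"rapid"}.
#' @param map a [genetic_map()]; required when the file lacks cM columns.
#' @param cols optional named integer vector overriding the dialect's column
#'   map; names among \code{id1, hap1, id2, hap2, chrom, start_bp, end_bp,
#'   start_cM, end_cM, length_cM}.
#' @param hap_sep separator when the haplotype index is encoded as a sample
#'   ID suffix (default \code{"."}).
#' @return a data frame of class \code{ibd_segments} with columns \code{id1,
#'   hap1, id2, hap2, chrom, start_cM, end_cM} (plus \code{start_bp,
#'   end_bp} when available), canonicalized and sorted.
#' @export
read_ibd_segments <- function(path, dialect = c("generic", "hap-ibd", "rapid"),
                              map = NULL, cols = NULL, hap_sep = ".") {
  dialect <- match.arg(dialect)
  if (dialect == "generic") {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    cm <- setNames(match(c("id1", "hap1", "id2", "hap2", "chrom", "start_bp",
                           "end_bp", "start_cM", "end_cM"), names(tab)),
                   c("id1", "hap1", "id2", "hap2", "chrom", "start_bp",
                     "end_bp", "start_cM", "end_cM"))
    cm <- cm[!is.na(cm)]
  } else {
    tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    cm <- if (dialect == "hap-ibd")
      c(id1 = 1L, hap1 = 2L, id2 = 3L, hap2 = 4L, chrom = 5L,
        start_bp = 6L, end_bp = 7L, length_cM = 8L)
    else
      c(chrom = 1L, id1 = 2L, id2 = 3L, hap1 = 4L, hap2 = 5L,
        start_bp = 6L, end_bp = 7L, start_cM = 8L, end_cM = 9L)
  }
  if (!is.null(cols)) cm[names(cols)] <- cols
  cm <- cm[cm <= ncol(tab)]
  need <- c("id1", "id2", "chrom")
  if (!all(need %in% names(cm)))
    stop("segment file is missing required columns: ",
         paste(setdiff(need, names(cm)), collapse = ", "))

  getcol <- function(nm) if (nm %in% names(cm)) tab[[cm[[nm]]]] else NULL
  id1 <- as.character(getcol("id1")); id2 <- as.character(getcol("id2"))
  hap1 <- getcol("hap1"); hap2 <- getcol("hap2")
  # haplotype encoded as an ID suffix ("ID.0") when no hap column exists
  split_hap <- function(id, hap) {
    if (!is.null(hap)) return(list(id = id, hap = as.integer(hap)))
    parts <- regmatches(id, regexpr(paste0("\\", hap_sep, "[01]$"), id))
    if (length(parts) == length(id) && all(nzchar(parts))) {
      list(id = sub(paste0("\\", hap_sep, "[01]$"), "", id),
           hap = as.integer(substring(parts, 2L)))
    } else list(id = id, hap = rep(0L, length(id)))
  }
  s1 <- split_hap(id1, hap1); s2 <- split_hap(id2, hap2)
  hap1 <- s1$hap; hap2 <- s2$hap; id1 <- s1$id; id2 <- s2$id
  if (dialect == "hap-ibd") { hap1 <- hap1 - 1L; hap2 <- hap2 - 1L }

  seg <- data.frame(id1 = id1, hap1 = hap1, id2 = id2, hap2 = hap2,
                    chrom = as.character(getcol("chrom")),
                    stringsAsFactors = FALSE)
  sb <- getcol("start_bp"); eb <- getcol("end_bp")
  if (!is.null(sb)) { seg$start_bp <- as.numeric(sb); seg$end_bp <- as.numeric(eb) }
  sc <- getcol("start_cM"); ec <- getcol("end_cM")
  if (!is.null(sc) && !is.null(ec)) {
    seg$start_cM <- as.numeric(sc); seg$end_cM <- as.numeric(ec)
  } else {
    if (is.null(map))
      stop("segment file carries no cM coordinates; a genetic map is required")
    seg$start_cM <- bp_to_cm(map, seg$chrom, seg$start_bp)
    seg$end_cM <- bp_to_cm(map, seg$chrom, seg$end_bp)
  }

  rejected <- c(bad_hap = 0L, self_pair = 0L, non_positive_length = 0L)
  ok <- rep(TRUE, nrow(seg))
  bad <- is.na(seg$hap1) | is.na(seg$hap2) | !(seg$hap1 %in% 0:1) |
    !(seg$hap2 %in% 0:1)
  rejected["bad_hap"] <- sum(bad); ok <- ok & !bad
  bad <- seg$id1 == seg$id2
  rejected["self_pair"] <- sum(bad & ok); ok <- ok & !bad
  bad <- !(seg$end_cM > seg$start_cM)
  if (!is.null(seg$start_bp))
    bad <- bad | (!is.na(seg$start_bp) & seg$end_bp <= seg$start_bp)
  bad[is.na(bad)] <- TRUE
  rejected["non_positive_length"] <- sum(bad & ok); ok <- ok & !bad
  if (any(!ok))
    message(sprintf("read_ibd_segments: rejected %d record(s) [%s]",
                    sum(!ok),
                    paste(sprintf("%s=%d", names(rejected), rejected),
                          collapse = ", ")))
  seg <- seg[ok, , drop = FALSE]
  seg <- canonicalize_segments(seg)
  attr(seg, "rejected") <- rejected
  class(seg) <- c("ibd_segments", "data.frame")
  seg
}

# Order each record so (id1, hap1) <= (id2, hap2) lexicographically,
# then sort rows for reproducible output.
canonicalize_segments <- function(seg) {
  k1 <- paste(seg$id1, seg$hap1, sep = "\r")
  k2 <- paste(seg$id2, seg$hap2, sep = "\r")
  swap <- k2 < k1
  if (any(swap)) {
    tmp <- seg$id1[swap]; seg$id1[swap] <- seg$id2[swap]; seg$id2[swap] <- tmp
    tmp <- seg$hap1[swap]; seg$hap1[swap] <- seg$hap2[swap]; seg$hap2[swap] <- tmp
  }
  seg <- seg[order(seg$chrom, seg$id1, seg$hap1, seg$id2, seg$hap2,
                   seg$start_cM, seg$end_cM), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Write IBD segments in the generic dialect
#'
#' @param seg an \code{ibd_segments} table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ibd_segments <- function(seg, path) {
  keep <- intersect(c("id1", "hap1", "id2", "hap2", "chrom",
                      "start_bp", "end_bp", "start_cM", "end_cM"),
                    names(seg))
  write.table(as.data.frame(seg)[keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Filter segments by genetic length
#'
#' Keeps segments with \code{end_cM - start_cM >= min_length_cM}; the
#' boundary is inclusive, matching callers that report segments at their
#' declared length cutoff.
#'
#' @param seg an \code{ibd_segments} table.
#' @param min_length_cM length cutoff in cM (default 3).
#' @return the filtered table.
#' @export
filter_segments <- function(seg, min_length_cM = 3) {
  stopifnot(min_length_cM >= 0)
  out <- seg[(seg$end_cM - seg$start_cM) >= min_length_cM, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a segment table directly from a data frame
#'
#' Validates and canonicalizes an in-memory data frame of segment calls
#' (columns as in the generic dialect of [read_ibd_segments()]).
#'
#' @param df data frame with at least \code{id1, hap1, id2, hap2, chrom,
#'   start_cM, end_cM}.
#' @return an \code{ibd_segments} table.
#' @export
ibd_segments <- function(df) {
  need <- c("id1", "hap1", "id2", "hap2", "chrom", "start_cM", "end_cM")
  stopifnot(all(need %in% names(df)))
  df$id1 <- as.character(df$id1); df$id2 <- as.character(df$id2)
  df$chrom <- as.character(df$chrom)
  if (any(df$id1 == df$id2)) stop("self-sharing segments are not allowed")
  if (any(df$end_cM <= df$start_cM)) stop("segments must have start_cM < end_cM")
  if (!all(df$hap1 %in% 0:1 & df$hap2 %in% 0:1))
    stop("haplotype indices must be 0 or 1")
  df <- canonicalize_segments(as.data.frame(df))
  class(df) <- c("ibd_segments", "data.frame")
  df
}
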