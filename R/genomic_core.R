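# Core data model: genome layout, annotations, binned tracks, interval math.
# Coordinates are 0-based half-open (BED convention) everywhere internally.

#' Genome layout
#'
#' Ordered chromosome names with lengths in bp. The total genome size `n`
#' enters the enrichment formula used for state features.
#'
#' @param chroms character vector of chromosome names.
#' @param lengths numeric vector of chromosome lengths in bp (same order).
#' @return An object of class `GenomeLayout`.
#' @export
genome_layout <- function(chroms, lengths) {
  stopifnot(length(chroms) == length(lengths), !anyDuplicated(chroms))
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  structure(
    list(chroms = as.character(chroms),
         lengths = stats::setNames(as.numeric(lengths), chroms)),
    class = "GenomeLayout")
}

#' Total genome size in bp
#' @param layout a `GenomeLayout`.
#' @return numeric scalar, the sum of chromosome lengths.
#' @export
genome_size <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  sum(layout$lengths)
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", length(x$chroms), "chromosomes,",
      format(genome_size(x), big.mark = ","), "bp\n")
  invisible(x)
}

# ---- interval sets ---------------------------------------------------------

.validate_intervals <- function(df, what = "interval set") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0) || any(df$end <= df$start))
    stop(what, ": requires 0 <= start < end for every interval")
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    if (is.unsorted(d$start))
      stop(what, ": intervals on ", ch, " are not sorted by start")
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop(what, ": intervals on ", ch, " overlap")
  }
  invisible(df)
}

.as_interval_df <- function(x) {
  if (inherits(x, "GRanges")) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
               start = GenomicRanges::start(x) - 1,
               end = GenomicRanges::end(x),
               stringsAsFactors = FALSE)
  } else if (inherits(x, "Annotation")) {
    x$segments[, c("chrom", "start", "end")]
  } else {
    as.data.frame(x)[, c("chrom", "start", "end")]
  }
}

.intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

#' Bases covered by both of two interval sets
#'
#' Both sets must be internally sorted and non-overlapping; the result is the
#' total number of bases covered by both (the `n_overlap` of the enrichment
#' formula), and is symmetric in its arguments.
#'
#' @param a,b interval sets: data frames with columns `chrom`, `start`,
#'   `end` (0-based half-open), `GRanges`, or `Annotation` objects.
#' @return numeric scalar base count.
#' @export
overlap_bases <- function(a, b) {
  da <- .validate_intervals(.as_interval_df(a), "overlap_bases 'a'")
  db <- .validate_intervals(.as_interval_df(b), "overlap_bases 'b'")
  shared <- intersect(da$chrom, db$chrom)
  da <- da[da$chrom %in% shared, , drop = FALSE]
  db <- db[db$chrom %in% shared, , drop = FALSE]
  if (nrow(da) == 0 || nrow(db) == 0) return(0)
  ov <- GenomicRanges::intersect(.intervals_to_gr(da), .intervals_to_gr(db),
                                 ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(ov)))
}

#' Total bases covered by an interval set
#' @param x an interval set (see [overlap_bases()]).
#' @return numeric scalar.
#' @export
covered_bases <- function(x) {
  df <- .as_interval_df(x)
  if (nrow(df) == 0) return(0)
  sum(df$end - df$start)
}

# ---- annotations -----------------------------------------------------------

#' Per-cell-type genome annotation with integer state labels
#'
#' A partition of (part of) a genome into ordered non-overlapping segments,
#' each carrying an integer state label in `[0, n_states)`, at a fixed bin
#' resolution (default 100 bp). Segment boundaries must be multiples of the
#' resolution.
#'
#' @param segments data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `state` (integer).
#' @param cell_type identifier for the annotated cell type.
#' @param resolution bin size in bp.
#' @param n_states number of states; defaults to `max(state) + 1`.
#' @return An object of class `Annotation`.
#' @export
annotation <- function(segments, cell_type, resolution = 100,
                       n_states = NULL) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(segments)))
  segments <- segments[, c("chrom", "start", "end", "state")]
  segments$chrom <- as.character(segments$chrom)
  segments$start <- as.numeric(segments$start)
  segments$end <- as.numeric(segments$end)
  segments$state <- as.integer(segments$state)
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  .validate_intervals(segments, "annotation segments")
  if (any(segments$start %% resolution != 0) ||
      any(segments$end %% resolution != 0))
    stop("segment boundaries must be multiples of the resolution (",
         resolution, " bp)")
  if (any(segments$state != floor(segments$state)) || any(segments$state < 0))
    stop("state labels must be non-negative integers")
  if (is.null(n_states)) n_states <- max(segments$state) + 1
  if (any(segments$state >= n_states))
    stop("state labels must be < n_states")
  structure(list(cell_type = cell_type, resolution = resolution,
                 n_states = as.integer(n_states), segments = segments),
            class = "Annotation")
}

#' @export
print.Annotation <- function(x, ...) {
  cat("Annotation of", x$cell_type, "-", nrow(x$segments), "segments,",
      x$n_states, "states,", x$resolution, "bp resolution\n")
  invisible(x)
}

#' State labels of the bins in a window
#'
#' Returns one state label per bin of the window, in genomic order. The
#' window must be aligned to the resolution grid and fully annotated.
#'
#' @param ann an `Annotation`.
#' @param chrom chromosome name.
#' @param start,end window boundaries in bp (0-based half-open), multiples of
#'   the annotation resolution.
#' @return integer vector of length `(end - start) / resolution`.
#' @export
bin_labels <- function(ann, chrom, start, end) {
  stopifnot(inherits(ann, "Annotation"))
  res <- ann$resolution
  if (start %% res != 0 || end %% res != 0)
    stop("window boundaries must be multiples of the resolution")
  if (end <= start) stop("window must have positive length")
  seg <- ann$segments[ann$segments$chrom == chrom, , drop = FALSE]
  seg <- seg[seg$end > start & seg$start < end, , drop = FALSE]
  if (nrow(seg) == 0)
    stop("window ", chrom, ":", start, "-", end, " is not annotated")
  s <- pmax(seg$start, start); e <- pmin(seg$end, end)
  if (s[1] > start)
    stop("window not fully annotated: gap at ", chrom, ":", start, "-", s[1])
  if (nrow(seg) > 1 && any(s[-1] != e[-nrow(seg)])) {
    i <- which(s[-1] != e[-nrow(seg)])[1]
    stop("window not fully annotated: gap at ", chrom, ":", e[i], "-", s[i + 1])
  }
  if (e[nrow(seg)] < end)
    stop("window not fully annotated: gap at ", chrom, ":", e[nrow(seg)],
         "-", end)
  rep(as.integer(seg$state), times = (e - s) / res)
}

#' Per-state covered intervals of an annotation
#' @param ann an `Annotation`.
#' @param state integer state label.
#' @return data frame of intervals covered by the state.
#' @export
state_intervals <- function(ann, state) {
  stopifnot(inherits(ann, "Annotation"))
  ann$segments[ann$segments$state == state, c("chrom", "start", "end"),
               drop = FALSE]
}

# ---- binned tracks ---------------------------------------------------------

#' Real-valued genomic track at fixed bin size
#'
#' Carrier for signal and conservation values. `values` holds one numeric
#' vector per chromosome; `NA` marks missing (masked) bins, which are
#' excluded from all statistics.
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param bin_size bin size in bp.
#' @return An object of class `BinnedTrack`.
#' @export
binned_track <- function(values, bin_size = 100) {
  stopifnot(is.list(values), !is.null(names(values)), bin_size > 0)
  values <- lapply(values, as.numeric)
  structure(list(bin_size = bin_size, values = values), class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  nb <- sum(vapply(x$values, length, 1L))
  nm <- sum(vapply(x$values, function(v) sum(is.na(v)), 1L))
  cat("BinnedTrack:", length(x$values), "chromosomes,", nb, "bins of",
      x$bin_size, "bp (", nm, "masked )\n")
  invisible(x)
}

#' All unmasked values of a track
#' @param track a `BinnedTrack`.
#' @return numeric vector.
#' @export
track_values <- function(track) {
  v <- unlist(track$values, use.names = FALSE)
  v[!is.na(v)]
}

#' Mask a track over a set of intervals
#'
#' Sets to `NA` every bin that overlaps the given intervals (e.g. an
#' exclusion list of unassembled or blacklisted regions).
#'
#' @param track a `BinnedTrack`.
#' @param intervals interval set (see [overlap_bases()]).
#' @return the masked `BinnedTrack`.
#' @export
mask_track <- function(track, intervals) {
  df <- .validate_intervals(.as_interval_df(intervals), "mask intervals")
  bs <- track$bin_size
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    if (!ch %in% names(track$values)) next
    b0 <- floor(df$start[i] / bs) + 1
    b1 <- ceiling(df$end[i] / bs)
    b1 <- min(b1, length(track$values[[ch]]))
    if (b0 <= b1) track$values[[ch]][b0:b1] <- NA_real_
  }
  track
}

#' Values of a track over the bins covered by an interval set
#' @param track a `BinnedTrack`.
#' @param intervals interval set aligned to the track's bin grid.
#' @param drop_na drop masked bins (default `TRUE`).
#' @return numeric vector of per-bin values.
#' @export
track_values_over <- function(track, intervals, drop_na = TRUE) {
  df <- .as_interval_df(intervals)
  bs <- track$bin_size
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    if (!ch %in% names(track$values))
      stop("track has no chromosome ", ch)
    b0 <- df$start[i] / bs + 1
    b1 <- df$end[i] / bs
    if (b0 != floor(b0) || b1 != floor(b1))
      stop("intervals must be aligned to the track bin grid")
    out[[i]] <- track$values[[ch]][b0:b1]
  }
  v <- unlist(out, use.names = FALSE)
  if (drop_na) v <- v[!is.na(v)]
  v
}
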