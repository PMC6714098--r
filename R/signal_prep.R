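# Signal normalization, cell-type similarity, missing-mark substitution,
# and the state-count formula.

#' Inverse hyperbolic sine transform of a track
#'
#' Elementwise `asinh(x) = ln(x + sqrt(x^2 + 1))`. Like a log transform it
#' compresses large values, but it is defined at zero and amplifies small
#' values less severely. Masks are preserved.
#'
#' @param track a `BinnedTrack`.
#' @return the transformed `BinnedTrack`.
#' @export
asinh_transform <- function(track) {
  stopifnot(inherits(track, "BinnedTrack"))
  track$values <- lapply(track$values, asinh)
  track
}

#' Genome-wide Z-score normalization of a track
#'
#' Subtracts the genome-wide mean and divides by the genome-wide
#' (population) standard deviation, over unmasked bins.
#'
#' @param track a `BinnedTrack`.
#' @return the normalized `BinnedTrack` (unmasked mean 0, sd 1).
#' @export
zscore_normalize <- function(track) {
  stopifnot(inherits(track, "BinnedTrack"))
  v <- track_values(track)
  if (length(v) < 2) stop("need at least 2 unmasked bins")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) stop("constant track: zero variance")
  track$values <- lapply(track$values, function(x) (x - mu) / sigma)
  track
}

# ---- track catalog ---------------------------------------------------------

#' Catalog of signal tracks by (cell type, assay type)
#'
#' Holds at most one representative track per (cell type, assay type) pair.
#'
#' @param tracks optional nested named list `tracks[[cell_type]][[assay]]`.
#' @return an object of class `TrackCatalog`.
#' @export
track_catalog <- function(tracks = list()) {
  structure(list(tracks = tracks), class = "TrackCatalog")
}

#' Add a track to a catalog
#' @param catalog a `TrackCatalog`.
#' @param cell_type,assay identifiers.
#' @param track a `BinnedTrack`.
#' @return the updated catalog.
#' @export
catalog_add <- function(catalog, cell_type, assay, track) {
  stopifnot(inherits(catalog, "TrackCatalog"), inherits(track, "BinnedTrack"))
  if (!is.null(catalog$tracks[[cell_type]][[assay]]))
    stop("catalog already has a representative track for (", cell_type,
         ", ", assay, ")")
  if (is.null(catalog$tracks[[cell_type]]))
    catalog$tracks[[cell_type]] <- list()
  catalog$tracks[[cell_type]][[assay]] <- track
  catalog
}

#' Cell types in a catalog
#' @param catalog a `TrackCatalog`.
#' @return character vector.
#' @export
catalog_cells <- function(catalog) names(catalog$tracks)

#' Assay types available for a cell type
#' @param catalog a `TrackCatalog`.
#' @param cell_type identifier.
#' @return character vector.
#' @export
catalog_assays <- function(catalog, cell_type)
  names(catalog$tracks[[cell_type]])

#' Fetch a track from a catalog
#' @param catalog a `TrackCatalog`.
#' @param cell_type,assay identifiers.
#' @return a `BinnedTrack`, or `NULL` when absent.
#' @export
catalog_get <- function(catalog, cell_type, assay)
  catalog$tracks[[cell_type]][[assay]]

#' @export
print.TrackCatalog <- function(x, ...) {
  cat("TrackCatalog:", length(x$tracks), "cell types,",
      sum(vapply(x$tracks, length, 1L)), "tracks\n")
  invisible(x)
}

#' Read a track catalog from a manifest
#'
#' Manifest is a TSV with header columns `cell_type`, `assay_type`, `path`,
#' `format`. Relative paths resolve against the manifest's directory.
#'
#' @param path manifest TSV.
#' @param layout a `GenomeLayout`.
#' @param bin_size bin size in bp.
#' @param normalize apply asinh + Z-score normalization on read.
#' @return a `TrackCatalog`.
#' @export
read_track_manifest <- function(path, layout, bin_size = 100,
                                normalize = FALSE) {
  man <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("cell_type", "assay_type", "path") %in% names(man)))
  if (is.null(man$format)) man$format <- "bedGraph"
  cat <- track_catalog()
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(dirname(path), man$path[i])
    tr <- read_track_bedgraph(p, layout, bin_size, format = man$format[i])
    if (normalize) tr <- zscore_normalize(asinh_transform(tr))
    cat <- catalog_add(cat, man$cell_type[i], man$assay_type[i], tr)
  }
  cat
}

# ---- similarity and substitution ------------------------------------------

#' Similarity between two cell types
#'
#' Mean genome-wide Pearson correlation over all assay types present in both
#' cell types, computed on jointly unmasked bins.
#'
#' @param catalog a `TrackCatalog` (tracks assumed normalized).
#' @param a,b cell-type identifiers.
#' @param min_shared_bins minimum jointly unmasked bins per shared assay
#'   (guards degenerate inputs).
#' @return numeric similarity in `[-1, 1]`.
#' @export
cell_type_similarity <- function(catalog, a, b, min_shared_bins = 1000) {
  shared <- intersect(catalog_assays(catalog, a), catalog_assays(catalog, b))
  if (length(shared) == 0)
    stop("no shared assay types between ", a, " and ", b,
         ": similarity undefined")
  rs <- vapply(shared, function(as_) {
    va <- unlist(catalog_get(catalog, a, as_)$values, use.names = FALSE)
    vb <- unlist(catalog_get(catalog, b, as_)$values, use.names = FALSE)
    ok <- !is.na(va) & !is.na(vb)
    if (sum(ok) < min_shared_bins)
      stop("fewer than ", min_shared_bins, " jointly unmasked bins for assay ",
           as_, " between ", a, " and ", b)
    stats::cor(va[ok], vb[ok])
  }, 1.0)
  mean(rs)
}

#' Substitute a missing assay from the most-similar cell type
#'
#' When a cell type lacks an assay, the track is borrowed from the cell type
#' with that assay available that is most similar to the target (ties broken
#' by lexicographically smaller donor name, for reproducibility).
#'
#' @param catalog a `TrackCatalog`.
#' @param target cell type missing the assay.
#' @param assay the missing assay type.
#' @param min_shared_bins passed to [cell_type_similarity()].
#' @return list with `donor` (cell type name), `track` (`BinnedTrack`) and
#'   `similarity`.
#' @export
select_substitute <- function(catalog, target, assay,
                              min_shared_bins = 1000) {
  cands <- setdiff(catalog_cells(catalog), target)
  cands <- cands[vapply(cands, function(cc)
    assay %in% catalog_assays(catalog, cc), TRUE)]
  cands <- cands[vapply(cands, function(cc)
    length(intersect(catalog_assays(catalog, target),
                     catalog_assays(catalog, cc))) > 0, TRUE)]
  if (length(cands) == 0)
    stop("no eligible donor cell type for missing assay ", assay,
         " (target ", target, ")")
  sims <- vapply(cands, function(cc)
    cell_type_similarity(catalog, target, cc, min_shared_bins), 1.0)
  ord <- order(-sims, cands)
  donor <- cands[ord[1]]
  list(donor = donor, track = catalog_get(catalog, donor, assay),
       similarity = sims[ord[1]])
}

#' Number of annotation states for a cell type
#'
#' `round(10 + 2 * sqrt(n_tracks))`, rounding half to even, so that model
#' complexity scales with the amount of input data. Over plausible track
#' counts (2-121) this spans 13-32 states.
#'
#' @param n_tracks number of available signal tracks (>= 1).
#' @return integer state count.
#' @export
num_states_for <- function(n_tracks) {
  if (any(n_tracks < 1)) stop("n_tracks must be >= 1")
  as.integer(round(10 + 2 * sqrt(n_tracks)))
}
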