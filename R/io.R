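#' Bin read intervals into a fixed-resolution density track
#'
#' Accumulates read (or bedGraph) intervals into consecutive bins of
#' \code{resolution} base pairs and converts counts to a depth- and
#' length-normalized density. Bin v covers base pairs
#' [(v-1) * resolution + 1, v * resolution], the last bin truncated at
#' \code{chromLength}. An interval overlapping several bins contributes to
#' each in proportion to the overlapped bases, so raw per-bin counts always
#' sum to the total input count. The density reported for a bin of length L
#' bp is \code{count / ((L / 1e6) * (total / 1e6))} with \code{total} the
#' summed input counts.
#'
#' @param intervals data.frame with columns \code{start}, \code{end}
#'   (1-based inclusive bp) and optionally \code{count} (default 1 per
#'   interval), or a \code{GRanges} (a \code{count} or \code{score}
#'   metadata column is used when present). May be empty.
#' @param chromLength chromosome length in bp.
#' @param resolution bin width in bp.
#' @param totalReads total mapped reads of the library used for depth
#'   normalization; defaults to the summed counts of \code{intervals}
#'   (appropriate when they cover the whole chromosome being binned).
#' @return numeric vector of per-bin densities, length
#'   \code{ceiling(chromLength / resolution)}.
#' @export
#' @examples
#' # one read among a million in the first 40 kb bin
#' binCoverage(data.frame(start = 1, end = 100), 80000, 40000,
#'   totalReads = 1e6
#' )
binCoverage <- function(intervals, chromLength, resolution,
                        totalReads = NULL) {
  stopifnot(resolution > 0, chromLength >= 1)
  nb <- as.integer(ceiling(chromLength / resolution))
  if (is(intervals, "GRanges")) {
    md <- S4Vectors::mcols(intervals)
    cnt <- if ("count" %in% colnames(md)) {
      md$count
    } else if ("score" %in% colnames(md)) {
      md$score
    } else {
      rep(1, length(intervals))
    }
    intervals <- data.frame(
      start = GenomicRanges::start(intervals),
      end = GenomicRanges::end(intervals),
      count = cnt
    )
  }
  if (is.null(intervals$count)) {
    intervals$count <- rep(1, nrow(intervals))
  }
  if (nrow(intervals) == 0L) {
    return(numeric(nb))
  }
  if (any(intervals$count < 0)) {
    stop("negative interval counts are not allowed")
  }
  if (any(intervals$start < 1 | intervals$end > chromLength |
    intervals$end < intervals$start)) {
    stop("intervals must lie within [1, chromLength]")
  }
  raw <- numeric(nb)
  for (k in seq_len(nrow(intervals))) {
    a <- intervals$start[k]
    b <- intervals$end[k]
    cnt <- intervals$count[k]
    len <- b - a + 1
    v1 <- ceiling(a / resolution)
    v2 <- ceiling(b / resolution)
    for (v in v1:v2) {
      lo <- max(a, (v - 1) * resolution + 1)
      hi <- min(b, v * resolution)
      raw[v] <- raw[v] + cnt * (hi - lo + 1) / len
    }
  }
  total <- if (is.null(totalReads)) sum(intervals$count) else totalReads
  stopifnot(total > 0)
  binLen <- rep(resolution, nb)
  binLen[nb] <- chromLength - (nb - 1) * resolution
  raw / ((binLen / 1e6) * (total / 1e6))
}

#' Log-transform a density matrix
#'
#' Elementwise \code{log(x + 1)}, damping the influence of extreme bins.
#'
#' @param densities non-negative numeric matrix or vector.
#' @return transformed object of the same shape.
#' @export
logTransform <- function(densities) {
  if (any(densities < 0)) {
    stop("densities must be non-negative")
  }
  log1p(densities)
}

#' Average replicate marker tracks
#'
#' Elementwise arithmetic mean of density matrices for the same track and
#' mark set, applied to raw (pre-log) densities to damp batch differences.
#'
#' @param matrices list of \linkS4class{MarkerMatrix} with identical
#'   dimensions and mark ordering.
#' @return a single \linkS4class{MarkerMatrix} (mMax recomputed).
#' @export
averageReplicates <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  ref <- matrices[[1L]]
  for (m in matrices[-1L]) {
    if (!identical(dim(m@densities), dim(ref@densities)) ||
      !identical(colnames(m@densities), colnames(ref@densities))) {
      stop("replicates must have identical dimensions and mark ordering")
    }
  }
  avg <- Reduce(`+`, lapply(matrices, densities)) / length(matrices)
  MarkerMatrix(avg,
    trackId = ref@trackId,
    resolutionBp = ref@resolutionBp
  )
}

#' Corpus-wide per-mark density maxima
#'
#' The maximum observed density of each mark across all tracks; marks that
#' are identically zero get maximum 1 so that normalization stays defined.
#'
#' @param tracks a \linkS4class{TrainingCorpus} or list of
#'   \linkS4class{MarkerMatrix}.
#' @return named numeric vector of per-mark maxima.
#' @export
computeMMax <- function(tracks) {
  if (is(tracks, "TrainingCorpus")) {
    tracks <- tracks@tracks
  }
  mm <- Reduce(pmax, lapply(tracks, function(H) apply(H@densities, 2, max)))
  mm[mm <= 0] <- 1
  mm
}

#' Normalize densities to the unit interval
#'
#' Divides by the per-mark maximum and clips to [0, 1]; clipping only
#' matters for test-time densities above the training maximum, since the
#' Bernstein basis is defined on [0, 1] only.
#'
#' @param c numeric vector/matrix of densities (columns = marks when a
#'   matrix).
#' @param mMax per-mark maxima (recycled over columns for a matrix).
#' @return normalized values in [0, 1], same shape as \code{c}.
#' @export
normalizeDensity <- function(c, mMax) {
  stopifnot(all(mMax > 0))
  p <- if (is.matrix(c)) sweep(c, 2L, mMax, "/") else c / mMax
  pmin(pmax(p, 0), 1)
}

#' Label every bin with its domain role
#'
#' Maps a partition to the four-state sequence of the chain: the first and
#' last bin of each domain become \code{sb} / \code{eb}, bins strictly
#' inside become \code{i}, and all remaining bins \code{e}.
#'
#' @param D a \linkS4class{DomainPartition}.
#' @param nBins optional override of the track length (defaults to
#'   \code{nBins(D)}).
#' @return character vector of states over \code{c("sb","i","eb","e")} with
#'   attribute \code{"classIndex"}: per-bin index into (b, i, e) with sb
#'   and eb pooled into b.
#' @seealso \code{\link{statesToPartition}} for the inverse.
#' @export
#' @examples
#' labelStates(DomainPartition(cbind(2, 4), 5))
labelStates <- function(D, nBins = NULL) {
  if (is.null(nBins)) nBins <- D@nBins
  stopifnot(validObject(D))
  states <- rep("e", nBins)
  d <- D@domains
  for (k in seq_len(nrow(d))) {
    s <- d[k, 1L]
    e <- d[k, 2L]
    states[s] <- "sb"
    states[e] <- "eb"
    if (e - s >= 2L) states[(s + 1L):(e - 1L)] <- "i"
  }
  idx <- c(sb = 1L, i = 2L, eb = 1L, e = 3L)[states]
  names(idx) <- NULL
  attr(states, "classIndex") <- idx
  states
}

#' Recover a domain partition from a state sequence
#'
#' Inverse of \code{\link{labelStates}}: consecutive runs from \code{sb}
#' to the next \code{eb} become domains. The sequence must respect the
#' chain's transition structure.
#'
#' @param states character vector over \code{c("sb","i","eb","e")}.
#' @param trackId track name for the result.
#' @return a \linkS4class{DomainPartition}.
#' @export
statesToPartition <- function(states, trackId = "track") {
  n <- length(states)
  ok <- transitionMatrix()
  if (!states[1L] %in% c("sb", "e") || !states[n] %in% c("eb", "e")) {
    stop("state sequence must start in {sb, e} and end in {eb, e}")
  }
  if (n > 1L) {
    pairs <- cbind(states[-n], states[-1L])
    if (any(ok[pairs] == 0L)) {
      stop("state sequence violates the transition structure")
    }
  }
  starts <- which(states == "sb")
  ends <- which(states == "eb")
  DomainPartition(cbind(starts, ends), n, trackId = trackId)
}

#' Class rebalancing weights for a training corpus
#'
#' Inverse-frequency weights over the three bin classes (boundary,
#' interior, inter-domain): \code{N_total / (3 * N_class)}, so a balanced
#' corpus gets unit weights. A class absent from the corpus gets weight 1.
#'
#' @param corpus a \linkS4class{TrainingCorpus}.
#' @return named numeric vector (b, i, e).
#' @export
computeClassWeights <- function(corpus) {
  counts <- c(b = 0, i = 0, e = 0)
  for (q in seq_along(corpus@tracks)) {
    idx <- attr(labelStates(corpus@partitions[[q]]), "classIndex")
    tab <- tabulate(idx, 3L)
    counts <- counts + tab
  }
  total <- sum(counts)
  cw <- ifelse(counts > 0, total / (3 * counts), 1)
  names(cw) <- .CLASSES
  cw
}

## ---- file formats -------------------------------------------------------

#' Read and write domain partitions as BED3
#'
#' On disk domains are 0-based half-open base-pair intervals; in memory
#' they are 1-based inclusive bin indices, so bin interval [s, e] maps to
#' bp [(s-1)*resolution, e*resolution). Intervals must align to the bin
#' grid and span at least two bins.
#'
#' @param path BED file path.
#' @param resolution bin width in bp.
#' @param nBins track length in bins; when NULL inferred as the last
#'   covered bin.
#' @param seqname chromosome name to read (default: first seen) or write.
#' @return \code{readDomainsBed}: a \linkS4class{DomainPartition}.
#' @export
readDomainsBed <- function(path, resolution, nBins = NULL, seqname = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) {
    stop("no intervals in BED file")
  }
  sn <- as.character(GenomicRanges::seqnames(gr))
  if (is.null(seqname)) seqname <- sn[1L]
  gr <- gr[sn == seqname]
  startBp <- GenomicRanges::start(gr) - 1L # back to 0-based
  endBp <- GenomicRanges::end(gr) # half-open end
  if (any(startBp %% resolution != 0) || any(endBp %% resolution != 0)) {
    stop("BED intervals must align to the bin resolution")
  }
  s <- startBp / resolution + 1L
  e <- endBp / resolution
  if (any(e - s < 1L)) {
    stop("BED intervals must span at least two bins")
  }
  if (is.null(nBins)) nBins <- max(e)
  DomainPartition(cbind(s, e), nBins, trackId = seqname)
}

#' @param D a \linkS4class{DomainPartition} to write.
#' @rdname readDomainsBed
#' @export
writeDomainsBed <- function(D, path, resolution, seqname = NULL) {
  if (is.null(seqname)) seqname <- D@trackId
  d <- D@domains
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(
      start = (d[, 1L] - 1L) * resolution + 1L,
      end = d[, 2L] * resolution
    )
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read and write marker matrices as TSV
#'
#' Tab-separated matrix with a header row of mark names, one row per bin,
#' and an optional leading \code{bin} index column. Densities are written
#' with 12 significant digits so round-trips are lossless at working
#' precision.
#'
#' @param path TSV file path.
#' @param trackId,resolutionBp metadata for the constructed object.
#' @return \code{readMarkerMatrix}: a \linkS4class{MarkerMatrix}.
#' @export
readMarkerMatrix <- function(path, trackId = "track", resolutionBp = 40000) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (colnames(df)[1L] == "bin") {
    df <- df[, -1L, drop = FALSE]
  }
  MarkerMatrix(as.matrix(df), trackId = trackId, resolutionBp = resolutionBp)
}

#' @param H a \linkS4class{MarkerMatrix} to write.
#' @rdname readMarkerMatrix
#' @export
writeMarkerMatrix <- function(H, path) {
  d <- H@densities
  out <- data.frame(bin = seq_len(nrow(d)), check.names = FALSE)
  for (m in colnames(d)) {
    out[[m]] <- format(d[, m], digits = 12, trim = TRUE, scientific = FALSE)
  }
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Restrict a corpus to a subset of marks
#'
#' @param corpus a \linkS4class{TrainingCorpus}.
#' @param marks character vector of mark names to keep (order preserved as
#'   given).
#' @return a new \linkS4class{TrainingCorpus} over the selected marks.
#' @export
subsetMarks <- function(corpus, marks) {
  stopifnot(all(marks %in% markNames(corpus)))
  tracks <- lapply(corpus@tracks, function(H) {
    MarkerMatrix(H@densities[, marks, drop = FALSE],
      trackId = H@trackId, resolutionBp = H@resolutionBp,
      mMax = corpus@mMax[marks]
    )
  })
  TrainingCorpus(tracks, corpus@partitions, mMax = corpus@mMax[marks])
}
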