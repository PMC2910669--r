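# Spatial-map creation, template matching, exact 1-D 3-means clustering of
# the correlations, and reconstruction of noise-suppressed activity.

.selectionError <- function(msg) {
  stop(structure(class = c("betaSiftSelectionError", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.rowVariances <- function(B) {
  rowSums((B - rowMeans(B))^2) / (ncol(B) - 1L)
}

#' Spatial map of one IMF across all channels
#'
#' The spatial map is the vector of Pearson correlation coefficients between
#' the IMF (decomposed at the channel of interest) and the raw epoch data at
#' every channel; it represents the IMF's scalp weight distribution.
#'
#' @param epoch an [EEGEpoch-class].
#' @param imf numeric vector of length `nSamples(epoch)`.
#' @return named numeric vector of per-channel correlations in `[-1, 1]`.
#' @seealso [templateCorrelation()], [selectIMFs()]
#' @export
spatialMap <- function(epoch, imf) {
  stopifnot(is(epoch, "EEGEpoch"))
  imf <- as.numeric(imf)
  if (length(imf) != ncol(epoch@data))
    stop("IMF length must match the epoch sample count", call. = FALSE)
  v <- .rowVariances(epoch@data)
  if (any(v <= 0))
    stop(sprintf("degenerate input: zero-variance channel(s) %s",
                 paste(epoch@channelLabels[v <= 0], collapse = ", ")),
         call. = FALSE)
  if (var(imf) <= 0)
    stop("degenerate input: IMF has zero variance", call. = FALSE)
  w <- as.numeric(cor(t(epoch@data), imf))
  names(w) <- epoch@channelLabels
  w
}

#' Correlation between a spatial map and the spatial template
#'
#' Pearson correlation over channels. When the map carries channel names
#' they are matched against the template's labels (order-insensitively);
#' otherwise positional alignment is assumed.
#'
#' @param map numeric vector as returned by [spatialMap()].
#' @param template a [SpatialTemplate-class].
#' @return correlation coefficient in `[-1, 1]`.
#' @export
templateCorrelation <- function(map, template) {
  stopifnot(is(template, "SpatialTemplate"))
  w <- template@weights
  if (!is.null(names(map))) {
    idx <- match(template@channelLabels, names(map))
    if (anyNA(idx))
      stop(sprintf("map is missing template channel(s): %s",
                   paste(template@channelLabels[is.na(idx)], collapse = ", ")),
           call. = FALSE)
    map <- map[idx]
  }
  if (length(map) != length(w))
    stop("map and template must cover the same channels", call. = FALSE)
  if (var(as.numeric(map)) <= 0 || var(w) <= 0)
    stop("degenerate input: constant map or template", call. = FALSE)
  as.numeric(cor(as.numeric(map), w))
}

# Exhaustive search over contiguous 3-partitions of the sorted values.
# Optimal 1-D k-means clusters are contiguous in sorted order, so this is
# the exact global optimum; J <= ~16 makes it trivial and deterministic.
.kmeans1d3 <- function(values) {
  J <- length(values)
  o <- order(values)
  s <- values[o]
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  wss <- function(a, b) {  # within-cluster SS of s[a..b]
    su <- cs[b] - if (a > 1L) cs[a - 1L] else 0
    sq <- cs2[b] - if (a > 1L) cs2[a - 1L] else 0
    sq - su^2 / (b - a + 1L)
  }
  best <- Inf
  bi <- bj <- 0L
  for (i in 1L:(J - 2L)) {
    w1 <- wss(1L, i)
    for (j in (i + 1L):(J - 1L)) {
      obj <- w1 + wss(i + 1L, j) + wss(j + 1L, J)
      if (obj < best) {
        best <- obj
        bi <- i
        bj <- j
      }
    }
  }
  grp <- integer(J)  # 1 = low values, 3 = high values (sorted order)
  grp[o[1L:bi]] <- 1L
  grp[o[(bi + 1L):bj]] <- 2L
  grp[o[(bj + 1L):J]] <- 3L
  mu <- vapply(1:3, function(g) mean(values[grp == g]), 0)
  list(group = grp, centroids = mu, objective = best)
}

#' Cluster template correlations into high/middle/low groups
#'
#' Partitions the per-IMF template correlations into three clusters by
#' K-means with K = 3. The clustering is realized as the exact global
#' optimum over contiguous partitions of the sorted values (optimal 1-D
#' clusters are contiguous), so it is deterministic and needs no random
#' restarts. Labels are assigned by descending centroid.
#'
#' @param rhos numeric vector of J >= 3 template correlations.
#' @return A [ClusterAssignment-class].
#' @examples
#' rho <- c(0.24, 0.35, 0.62, 0.81, 0.30, -0.03, 0.24, 0.33, 0.40)
#' a <- clusterCorrelations(rho)
#' which(a@labels == "high")  # IMFs 3 and 4
#' @export
clusterCorrelations <- function(rhos) {
  rhos <- as.numeric(rhos)
  if (length(rhos) < 3L)
    .selectionError("need at least 3 correlation values for 3-means")
  if (!all(is.finite(rhos)))
    stop("correlations must be finite", call. = FALSE)
  if (diff(range(rhos)) <= 0)
    .selectionError("degenerate clustering: all correlations identical")
  k <- .kmeans1d3(rhos)
  lab <- c("low", "middle", "high")[k$group]
  new("ClusterAssignment", labels = lab,
      centroids = c(high = k$centroids[3], middle = k$centroids[2],
                    low = k$centroids[1]),
      objective = k$objective)
}

#' Select sensorimotor-related IMFs by spatial-template matching
#'
#' Builds the spatial map of every IMF, correlates each map with the
#' template, clusters the correlations into high/middle/low groups and
#' returns the indices of the highly-correlated group. With fewer than
#' three IMFs the three clusters cannot be formed; the fallback selects the
#' single best IMF provided its correlation reaches `rhoFloor`, else the
#' trial is flagged unusable (a selection error condition). The monotonic
#' residue never enters the selection.
#'
#' @param imfset an [IMFSet-class] decomposed from the CI row of `epoch`.
#' @param epoch the [EEGEpoch-class] the IMFs came from.
#' @param template a [SpatialTemplate-class].
#' @param rhoFloor minimum correlation accepted by the J < 3 fallback.
#' @return list with `selected` (integer indices into the IMF set),
#'   `correlations` (all rho values), `assignment` (a
#'   [ClusterAssignment-class], or `NULL` when the fallback ran) and
#'   `fallback` (logical).
#' @export
selectIMFs <- function(imfset, epoch, template, rhoFloor = 0.5) {
  stopifnot(is(imfset, "IMFSet"), is(epoch, "EEGEpoch"),
            is(template, "SpatialTemplate"))
  J <- nrow(imfset@imfs)
  if (J < 1L)
    .selectionError("no IMFs were extracted; nothing to select")
  v <- .rowVariances(epoch@data)
  if (any(v <= 0))
    stop(sprintf("degenerate input: zero-variance channel(s) %s",
                 paste(epoch@channelLabels[v <= 0], collapse = ", ")),
         call. = FALSE)
  maps <- cor(t(epoch@data), t(imfset@imfs))  # M x J in one pass
  rownames(maps) <- epoch@channelLabels
  rhos <- vapply(seq_len(J), function(j)
    templateCorrelation(maps[, j], template), 0)
  if (J < 3L) {
    best <- which.max(rhos)
    if (rhos[best] < rhoFloor)
      .selectionError(sprintf(
        "fewer than 3 IMFs and best correlation %.3f below floor %.3f",
        rhos[best], rhoFloor))
    return(list(selected = best, correlations = rhos, assignment = NULL,
                fallback = TRUE))
  }
  assignment <- clusterCorrelations(rhos)
  sel <- which(assignment@labels == "high")
  list(selected = sel, correlations = rhos, assignment = assignment,
       fallback = FALSE)
}

#' Reconstruct noise-suppressed activity from selected IMFs
#'
#' In `"ci"` mode the selected IMFs are summed, giving the noise-suppressed
#' signal at the channel of interest. In `"multichannel"` mode every
#' channel's epoch data is projected onto each selected IMF by least
#' squares (`beta(i, k) = cov(b_i, c_k) / var(c_k)`) and the weighted IMFs
#' are summed per channel, extending the reconstruction over the whole
#' montage; the CI row of the multichannel result approaches the CI-mode
#' sum when the IMFs are mutually near-orthogonal. The residue is never
#' included.
#'
#' @param imfset an [IMFSet-class].
#' @param selected nonempty integer indices of the chosen IMFs.
#' @param epoch the source [EEGEpoch-class]; required in multichannel mode.
#' @param mode `"multichannel"` or `"ci"`.
#' @return numeric vector (ci mode) or channels-by-samples matrix
#'   (multichannel mode, with channel rownames).
#' @export
reconstructSignal <- function(imfset, selected, epoch = NULL,
                              mode = c("multichannel", "ci")) {
  mode <- match.arg(mode)
  stopifnot(is(imfset, "IMFSet"))
  selected <- as.integer(selected)
  if (length(selected) == 0L)
    stop("selected IMF index set is empty; refusing to reconstruct",
         call. = FALSE)
  J <- nrow(imfset@imfs)
  if (any(selected < 1L | selected > J))
    stop(sprintf("selected indices must lie in 1..%d", J), call. = FALSE)
  C <- imfset@imfs[selected, , drop = FALSE]
  if (mode == "ci") return(as.numeric(colSums(C)))
  if (is.null(epoch))
    stop("multichannel reconstruction needs the source epoch", call. = FALSE)
  stopifnot(is(epoch, "EEGEpoch"))
  beta <- .projectionCoefficients(C, epoch)
  out <- beta %*% C
  rownames(out) <- epoch@channelLabels
  out
}

# least-squares projection coefficients beta(i, k) = cov(b_i, c_k)/var(c_k)
.projectionCoefficients <- function(C, epoch) {
  if (ncol(epoch@data) != ncol(C))
    stop("epoch and IMF sample counts differ", call. = FALSE)
  Cc <- C - rowMeans(C)
  den <- rowSums(Cc^2)
  if (any(den <= 0))
    stop("degenerate input: selected IMF with zero variance", call. = FALSE)
  Bc <- epoch@data - rowMeans(epoch@data)
  (Bc %*% t(Cc)) / rep(den, each = nrow(Bc))
}
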