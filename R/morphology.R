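#' Construct a neuron morphology object
#'
#' A `neuron_morphology` is a rooted 3-D reconstruction of a single cell:
#' a soma centroid plus zero or more neurites. Each neurite is a rooted tree
#' of 3-D points; the first segment of a neurite runs from the soma centroid
#' to the neurite's first node, so neurite path lengths include the somatic
#' attachment segment.
#'
#' @param cell_id character scalar identifying the cell.
#' @param soma numeric length-3 vector, soma centroid (x, y, z) in micrometres.
#' @param neurites list of neurite node tables. Each element is a data.frame
#'   with numeric columns `x`, `y`, `z`, `radius` and integer column `parent`;
#'   `parent` indexes the parent row within the same neurite, with `0` meaning
#'   the soma centroid. Row 1 must have `parent == 0`.
#' @param metadata named list of cell-level labels (species, line, batch, day).
#'   When a `day` is supplied it must be one of 7, 14, 21, 35.
#'
#' @return An object of class `neuron_morphology`.
#' @export
neuron_morphology <- function(cell_id, soma, neurites = list(),
                              metadata = list()) {
  stopifnot(is.character(cell_id), length(cell_id) == 1L)
  soma <- as.numeric(soma)
  if (length(soma) != 3L || !all(is.finite(soma)))
    stop("soma centroid must be 3 finite coordinates")
  neurites <- lapply(neurites, validate_neurite)
  if (!is.null(metadata$day) && !metadata$day %in% c(7, 14, 21, 35))
    stop("day must be one of 7, 14, 21, 35")
  structure(list(cell_id = cell_id, soma = soma, neurites = neurites,
                 metadata = metadata),
            class = "neuron_morphology")
}

validate_neurite <- function(n) {
  n <- as.data.frame(n)
  req <- c("x", "y", "z", "parent")
  if (!all(req %in% names(n))) stop("neurite needs columns x, y, z, parent")
  if (is.null(n$radius)) n$radius <- 0.2
  if (!all(is.finite(n$x)) || !all(is.finite(n$y)) || !all(is.finite(n$z)))
    stop("neurite coordinates must be finite")
  if (any(n$radius < 0)) stop("radius must be >= 0")
  p <- as.integer(n$parent)
  if (nrow(n) < 1L) stop("neurite must have at least one node")
  if (p[1] != 0L) stop("first neurite node must attach to the soma (parent 0)")
  if (any(p < 0L) || any(p > nrow(n)))
    stop("neurite parent index out of range")
  if (any(p[-1] >= seq_len(nrow(n))[-1]))
    stop("neurite nodes must be topologically ordered (parent before child)")
  n$parent <- p
  n[, c("x", "y", "z", "radius", "parent")]
}

#' @export
print.neuron_morphology <- function(x, ...) {
  cat(sprintf("<neuron_morphology> %s: %d neurite(s), %d nodes\n",
              x$cell_id, length(x$neurites),
              sum(vapply(x$neurites, nrow, 0L))))
  invisible(x)
}

# parent coordinates of every node in a neurite (soma for parent == 0)
neurite_parent_coords <- function(neurite, soma) {
  xyz <- as.matrix(neurite[, c("x", "y", "z")])
  p <- neurite$parent
  out <- matrix(soma, nrow = nrow(neurite), ncol = 3, byrow = TRUE)
  has_parent <- p > 0L
  out[has_parent, ] <- xyz[p[has_parent], , drop = FALSE]
  out
}

neurite_segments <- function(m) {
  segs <- lapply(m$neurites, function(n) {
    a <- neurite_parent_coords(n, m$soma)
    b <- as.matrix(n[, c("x", "y", "z")])
    cbind(a, b)
  })
  do.call(rbind, c(segs, list(matrix(numeric(0), ncol = 6))))
}

neurite_length <- function(neurite, soma) {
  a <- neurite_parent_coords(neurite, soma)
  b <- as.matrix(neurite[, c("x", "y", "z")])
  sum(sqrt(rowSums((b - a)^2)))
}

#' Total neurite length of a reconstruction
#'
#' Sum over all neurites of the parent-child Euclidean segment lengths
#' (including each neurite's somatic attachment segment).
#'
#' @param m a [neuron_morphology()].
#' @return Total length in micrometres.
#' @export
total_neurite_length <- function(m) {
  stopifnot(inherits(m, "neuron_morphology"))
  if (length(m$neurites) == 0L)
    stop("total_neurite_length is undefined for a cell with zero neurites")
  sum(vapply(m$neurites, neurite_length, 0, soma = m$soma))
}

#' Identify the axon as the longest neurite
#'
#' The operational axon definition: the neurite of maximal total path length.
#' Ties are broken deterministically in favour of the lowest neurite index.
#'
#' @param m a [neuron_morphology()].
#' @return list with `index` (neurite index) and `length` (micrometres).
#' @export
identify_axon <- function(m) {
  stopifnot(inherits(m, "neuron_morphology"))
  if (length(m$neurites) == 0L) stop("cell has no neurites")
  len <- vapply(m$neurites, neurite_length, 0, soma = m$soma)
  i <- which.max(len)  # which.max returns the first maximum
  list(index = i, length = len[i])
}

#' Classify somatic polarity
#'
#' Counts primary neurites (total path length >= `min_primary_length`) and
#' maps 1 to "unipolar", 2 to "bipolar" and >= 3 to "multipolar".
#'
#' @param m a [neuron_morphology()].
#' @param min_primary_length minimum neurite length (micrometres) for a
#'   neurite to count as primary. Default 5.
#' @return One of `"unipolar"`, `"bipolar"`, `"multipolar"`, or `NA` (with a
#'   warning) when no neurite qualifies.
#' @export
classify_polarity <- function(m, min_primary_length = 5) {
  stopifnot(inherits(m, "neuron_morphology"))
  if (length(m$neurites) == 0L) stop("cell has no neurites")
  len <- vapply(m$neurites, neurite_length, 0, soma = m$soma)
  k <- sum(len >= min_primary_length)
  if (k == 0L) {
    warning(sprintf("cell %s: no neurite reaches min_primary_length = %g; unclassifiable",
                    m$cell_id, min_primary_length))
    return(NA_character_)
  }
  if (k == 1L) "unipolar" else if (k == 2L) "bipolar" else "multipolar"
}

# number of times the distance to `centre` along segment a->b crosses radius r.
# d^2(t) is quadratic in t; crossings are the sign-changing roots of
# d^2(t) - r^2 in (0, 1]. Vectorized over segments for one radius.
segment_sphere_crossings <- function(a, b, centre, r) {
  u <- a - matrix(centre, nrow(a), 3, byrow = TRUE)
  v <- b - a
  A <- rowSums(v * v)
  B <- 2 * rowSums(u * v)
  C <- rowSums(u * u) - r^2
  n <- nrow(a)
  cnt <- integer(n)
  disc <- B^2 - 4 * A * C
  ok <- A > 0 & disc > 0
  if (!any(ok)) return(cnt)
  sq <- sqrt(disc[ok])
  t1 <- (-B[ok] - sq) / (2 * A[ok])
  t2 <- (-B[ok] + sq) / (2 * A[ok])
  cnt[ok] <- (t1 > 0 & t1 <= 1) + (t2 > 0 & t2 <= 1)
  cnt
}

#' Sholl profile of a reconstruction
#'
#' Counts intersections of the neurite arbor with concentric spheres of
#' increasing radius centred on the soma centroid. Every crossing of a
#' parent-child segment through a sphere is counted (a segment that enters
#' and leaves a shell contributes two crossings at that radius).
#'
#' @param m a [neuron_morphology()].
#' @param step radius increment in micrometres (default 10).
#' @param max_radius largest radius; `NULL` (default) extends to the furthest
#'   node from the soma.
#' @return list of class `sholl_profile`: `radii`, `counts`,
#'   `total_intersections`.
#' @export
sholl_profile <- function(m, step = 10, max_radius = NULL) {
  stopifnot(inherits(m, "neuron_morphology"))
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("sholl step must be a positive number")
  segs <- neurite_segments(m)
  if (nrow(segs) == 0L) {
    out <- list(radii = numeric(0), counts = integer(0), total_intersections = 0L)
    class(out) <- "sholl_profile"
    return(out)
  }
  a <- segs[, 1:3, drop = FALSE]
  b <- segs[, 4:6, drop = FALSE]
  dmax <- sqrt(max(rowSums((b - matrix(m$soma, nrow(b), 3, byrow = TRUE))^2),
                   rowSums((a - matrix(m$soma, nrow(a), 3, byrow = TRUE))^2)))
  if (is.null(max_radius)) max_radius <- dmax
  radii <- seq(step, max_radius, by = step)
  counts <- vapply(radii, function(r)
    sum(segment_sphere_crossings(a, b, m$soma, r)), 0L)
  out <- list(radii = radii, counts = as.integer(counts),
              total_intersections = sum(as.integer(counts)))
  class(out) <- "sholl_profile"
  out
}

#' Full morphometry record for one cell
#'
#' Computes the per-cell morphometric quantities: polarity class, total
#' neurite length, axon (longest-neurite) length, dendrite length
#' (total minus axon) and the Sholl profile.
#'
#' @param m a [neuron_morphology()].
#' @param step Sholl radius step, micrometres.
#' @param min_primary_length polarity threshold, micrometres.
#' @return list of class `morphometry_record` with fields `cell_id`,
#'   `polarity_class`, `n_neurites`, `total_neurite_length`, `axon_index`,
#'   `axon_length`, `dendrite_length`, `sholl`, `metadata`.
#' @export
morphometry <- function(m, step = 10, min_primary_length = 5) {
  stopifnot(inherits(m, "neuron_morphology"))
  if (length(m$neurites) == 0L) stop("cell has no neurites")
  total <- total_neurite_length(m)
  axon <- identify_axon(m)
  rec <- list(cell_id = m$cell_id,
              polarity_class = classify_polarity(m, min_primary_length),
              n_neurites = length(m$neurites),
              total_neurite_length = total,
              axon_index = axon$index,
              axon_length = axon$length,
              dendrite_length = total - axon$length,
              sholl = sholl_profile(m, step = step),
              metadata = m$metadata)
  class(rec) <- "morphometry_record"
  rec
}

#' Tabulate morphometry records
#'
#' @param records list of `morphometry_record` objects.
#' @return list with `cells` (one row per cell) and `sholl` (long format:
#'   cell_id, radius, count) data.frames.
#' @export
morphometry_table <- function(records) {
  cells <- do.call(rbind, lapply(records, function(r) {
    md <- r$metadata
    data.frame(cell_id = r$cell_id,
               species = md$species %||% NA_character_,
               line = md$line %||% NA_character_,
               batch = md$batch %||% NA_character_,
               day = md$day %||% NA_real_,
               polarity_class = r$polarity_class,
               n_neurites = r$n_neurites,
               total_neurite_length = r$total_neurite_length,
               axon_length = r$axon_length,
               dendrite_length = r$dendrite_length,
               sholl_total = r$sholl$total_intersections,
               stringsAsFactors = FALSE)
  }))
  sholl <- do.call(rbind, lapply(records, function(r) {
    if (length(r$sholl$radii) == 0L) return(NULL)
    data.frame(cell_id = r$cell_id, radius = r$sholl$radii,
               count = r$sholl$counts, stringsAsFactors = FALSE)
  }))
  list(cells = cells, sholl = sholl)
}

#' Per-batch normalization against a reference group
#'
#' Divides each value by the mean of the reference-group (default "ape")
#' values in its batch, so that the reference group's per-batch mean of
#' normalized values is exactly 1.
#'
#' @param df data.frame with at least columns `group`, `batch`, `value`.
#' @param ref_group group label used as the per-batch denominator.
#' @return `df` with an added `normalized` column.
#' @export
batch_normalize <- function(df, ref_group = "ape") {
  stopifnot(is.data.frame(df), all(c("group", "batch", "value") %in% names(df)))
  out <- df
  out$normalized <- NA_real_
  for (b in unique(df$batch)) {
    in_b <- df$batch == b
    ref <- df$value[in_b & df$group == ref_group]
    if (length(ref) == 0L)
      stop(sprintf("batch '%s' has no %s values to normalize against", b, ref_group))
    out$normalized[in_b] <- df$value[in_b] / mean(ref)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
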