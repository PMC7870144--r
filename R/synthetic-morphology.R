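#' Parameters for the synthetic morphology generator
#'
#' The generator emulates neurite arbors growing over differentiation days:
#' a cell has 1-5 primary neurites, each a stochastic branching tree whose
#' segment lengths scale multiplicatively with day (`elongation_per_day`),
#' species and batch.
#'
#' @param n_primary fixed number of primary neurites, or `NULL` to sample
#'   from `primary_probs` (classes 1..5; defaults give roughly 6% unipolar,
#'   30% bipolar, 64% multipolar cells, matching observed polarity
#'   proportions in induced-neuron cultures).
#' @param primary_probs sampling weights for 1..5 primary neurites.
#' @param branch_prob probability that a segment ends in a bifurcation.
#' @param segment_length mean segment length at day 7, micrometres.
#' @param segment_length_sd SD of segment lengths, micrometres.
#' @param node_spacing approximate spacing of 3-D points along a segment,
#'   micrometres.
#' @param elongation_per_day multiplicative growth factor per day after d7.
#' @param species_scale,batch_scale multiplicative length scales.
#' @param max_depth maximum branch depth.
#' @return list of class `morph_gen_params`.
#' @export
morph_gen_params <- function(n_primary = NULL,
                             primary_probs = c(0.06, 0.30, 0.34, 0.20, 0.10),
                             branch_prob = 0.35,
                             segment_length = 30, segment_length_sd = 10,
                             node_spacing = 3,
                             elongation_per_day = 1.05,
                             species_scale = 1, batch_scale = 1,
                             max_depth = 4) {
  stopifnot(branch_prob >= 0, branch_prob <= 1,
            species_scale > 0, batch_scale > 0, segment_length > 0)
  structure(as.list(environment()), class = "morph_gen_params")
}

runit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# rotate v by `angle` radians about a random axis perpendicular to it
perturb_direction <- function(v, angle) {
  a <- runit_vector()
  a <- a - sum(a * v) * v
  na <- sqrt(sum(a^2))
  if (na < 1e-12) return(v)
  a <- a / na
  w <- cos(angle) * v + sin(angle) * a
  w / sqrt(sum(w^2))
}

#' Generate one ground-truthed synthetic neuron morphology
#'
#' @param params a [morph_gen_params()].
#' @param day differentiation day (7, 14, 21 or 35).
#' @param cell_id cell identifier.
#' @param metadata extra cell labels (species, line, batch); `day` is added.
#' @param seed optional RNG seed for reproducibility.
#' @return list with `morphology` (a [neuron_morphology()]) and `truth`:
#'   `total_length`, `neurite_lengths`, `n_neurites`, `n_nodes`,
#'   `n_branch_points`, `polarity_class` (at the default 5 um primary
#'   threshold).
#' @export
generate_morphology <- function(params = morph_gen_params(), day = 7,
                                cell_id = "synthetic_cell",
                                metadata = list(), seed = NULL) {
  stopifnot(inherits(params, "morph_gen_params"))
  if (!is.null(seed)) set.seed(seed)
  scale <- params$species_scale * params$batch_scale *
    params$elongation_per_day^(day - 7)
  soma <- c(0, 0, 0)
  n_prim <- if (is.null(params$n_primary))
    sample(seq_along(params$primary_probs), 1, prob = params$primary_probs)
  else params$n_primary

  neurites <- vector("list", n_prim)
  neurite_lengths <- numeric(n_prim)
  n_branches <- 0L
  for (i in seq_len(n_prim)) {
    nodes <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        radius = numeric(0), parent = integer(0))
    total <- 0
    # stack of growth fronts: list(pos, dir, parent_idx, depth)
    stack <- list(list(pos = soma, dir = runit_vector(), parent = 0L, depth = 0L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      seg_len <- max(2, stats::rnorm(1, params$segment_length,
                                     params$segment_length_sd)) * scale
      npts <- max(2L, ceiling(seg_len / params$node_spacing))
      step <- seg_len / npts
      pos <- fr$pos; dir <- fr$dir; parent <- fr$parent
      for (k in seq_len(npts)) {
        dir <- perturb_direction(dir, stats::rnorm(1, 0, 0.12))
        pos <- pos + dir * step
        total <- total + step
        nodes <- rbind(nodes, data.frame(x = pos[1], y = pos[2], z = pos[3],
                                         radius = 0.2, parent = parent))
        parent <- nrow(nodes)
      }
      if (fr$depth < params$max_depth &&
          stats::runif(1) < params$branch_prob) {
        n_branches <- n_branches + 1L
        for (ang in c(0.6, -0.6)) {
          stack[[length(stack) + 1L]] <-
            list(pos = pos, dir = perturb_direction(dir, ang + stats::rnorm(1, 0, 0.1)),
                 parent = parent, depth = fr$depth + 1L)
        }
      }
    }
    neurites[[i]] <- nodes
    neurite_lengths[i] <- total
  }
  metadata$day <- day
  m <- neuron_morphology(cell_id, soma, neurites, metadata)
  k <- sum(neurite_lengths >= 5)
  truth <- list(
    total_length = sum(neurite_lengths),
    neurite_lengths = neurite_lengths,
    n_neurites = n_prim,
    n_nodes = sum(vapply(neurites, nrow, 0L)),
    n_branch_points = n_branches,
    polarity_class = if (k == 0) NA_character_ else if (k == 1) "unipolar"
    else if (k == 2) "bipolar" else "multipolar")
  list(morphology = m, truth = truth)
}

#' Dense-resampling Sholl reference
#'
#' Reference implementation of the Sholl intersection count: every segment
#' is resampled at `ds` micrometre resolution and crossings are counted as
#' sign changes of (distance to soma - radius) along the resampled path.
#' Slow but assumption-free; used as the independent check of
#' [sholl_profile()].
#'
#' @param m a [neuron_morphology()].
#' @param step radius increment, micrometres.
#' @param max_radius largest radius (default: furthest node).
#' @param ds resampling resolution, micrometres.
#' @return list: `radii`, `counts`, `total_intersections`.
#' @export
sholl_profile_dense <- function(m, step = 10, max_radius = NULL, ds = 0.01) {
  segs <- neurite_segments(m)
  if (nrow(segs) == 0L)
    return(list(radii = numeric(0), counts = integer(0), total_intersections = 0L))
  a <- segs[, 1:3, drop = FALSE]; b <- segs[, 4:6, drop = FALSE]
  dmax <- sqrt(max(rowSums((b - matrix(m$soma, nrow(b), 3, byrow = TRUE))^2),
                   rowSums((a - matrix(m$soma, nrow(a), 3, byrow = TRUE))^2)))
  if (is.null(max_radius)) max_radius <- dmax
  radii <- seq(step, max_radius, by = step)
  counts <- integer(length(radii))
  for (s in seq_len(nrow(segs))) {
    p0 <- a[s, ]; p1 <- b[s, ]
    len <- sqrt(sum((p1 - p0)^2))
    if (len == 0) next
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / ds) + 1L))
    pts <- outer(ts, p1 - p0) + matrix(p0, length(ts), 3, byrow = TRUE)
    d <- sqrt(rowSums((pts - matrix(m$soma, length(ts), 3, byrow = TRUE))^2))
    for (j in seq_along(radii)) {
      sgn <- d - radii[j] > 0
      counts[j] <- counts[j] + sum(sgn[-1] != sgn[-length(sgn)])
    }
  }
  list(radii = radii, counts = counts, total_intersections = sum(counts))
}
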