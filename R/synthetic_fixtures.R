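# Synthetic coordinate fixtures with known ground truth: ideal flat/curved
# beta-sheets with prescribed orientation and shift, random peptide gases,
# and clustered aggregates.  Every generator is deterministic under a fixed
# seed.
#
# Geometry of the ideal sheet: strands run along x with one grain per
# residue spaced by `rise` (default 3.4 A, the beta-strand rise).  Adjacent
# strands are stacked at `spacing` (default 4.8 A, inside the 4.7-5.3 A
# beta-contact window) along a stacking direction in the (y, z) plane that
# rotates by `twist` degrees per strand about the sheet's long axis,
# emulating the curved/saddle shape of natural sheets while keeping every
# registered inter-strand distance exactly equal to `spacing`.
#
# Registry bookkeeping: strand s has a direction d_s (+1, or -1 when
# reversed by an antiparallel step) and an offset o_s in residue units.
# With rows of a pair submatrix indexed by the lower strand p, the designed
# alignment of adjacent pair (p, q = p+1) maps onto the template library as
#   parallel:      o_q = o_p - d_p * k
#   antiparallel:  o_q = o_p + d_p * k
# which the generator inverts to realize any requested (orientation, k).

#' Generate an ideal beta-sheet with prescribed registries
#'
#' @param n_strands Number of strands (>= 2).
#' @param SL Residues (grains) per strand (>= 3).
#' @param orientation Per-adjacent-pair orientation, `"parallel"` or
#'   `"antiparallel"`; recycled to `n_strands - 1`.
#' @param shift Per-adjacent-pair designed shift k (|k| <= SL - 3);
#'   recycled likewise.
#' @param spacing Inter-strand distance, Angstrom; must lie inside the
#'   contact window for the sheet to produce contacts.
#' @param rise Per-residue rise along the strand axis, Angstrom.
#' @param twist Degrees of stacking-direction rotation per strand.
#' @param jitter Per-coordinate Gaussian noise sd, truncated at ±`jitter`
#'   Angstrom (0 = exact geometry).
#' @param seed RNG seed used when `jitter > 0`.
#' @return List with `frame` ([backbone_frame]), `topology`
#'   ([system_topology]) and `ground_truth` (data.frame of p, q,
#'   orientation, k for each adjacent pair, rows indexed by strand p).
#' @export
make_ideal_sheet <- function(n_strands, SL,
                             orientation = "parallel", shift = 0L,
                             spacing = 4.8, rise = 3.4, twist = 0,
                             jitter = 0, seed = 1L) {
  n_strands <- as.integer(n_strands); SL <- as.integer(SL)
  if (n_strands < 2L) stop("need at least 2 strands")
  if (SL < 3L) stop("SL must be >= 3")
  n_pairs <- n_strands - 1L
  orientation <- rep_len(match.arg(orientation,
                                   c("parallel", "antiparallel"),
                                   several.ok = TRUE), n_pairs)
  shift <- rep_len(as.integer(shift), n_pairs)
  if (any(abs(shift) > SL - 3L))
    stop("designed |shift| must be <= SL - 3")
  if (jitter < 0) stop("jitter must be >= 0")

  dirs <- integer(n_strands); offs <- numeric(n_strands)
  dirs[1] <- 1L; offs[1] <- 0
  for (p in seq_len(n_pairs)) {
    if (orientation[p] == "parallel") {
      dirs[p + 1L] <- dirs[p]
      offs[p + 1L] <- offs[p] - dirs[p] * shift[p]
    } else {
      dirs[p + 1L] <- -dirs[p]
      offs[p + 1L] <- offs[p] + dirs[p] * shift[p]
    }
  }
  # stacking positions in the (y, z) plane
  tw <- twist * pi / 180
  ctr <- matrix(0, n_strands, 2)
  for (s in seq_len(n_strands - 1L)) {
    ang <- (s - 1L) * tw
    ctr[s + 1L, ] <- ctr[s, ] + spacing * c(cos(ang), sin(ang))
  }
  coords <- matrix(0, n_strands * SL, 3)
  for (s in seq_len(n_strands)) {
    i <- seq_len(SL)
    axis_pos <- if (dirs[s] > 0) offs[s] + (i - 1L) else offs[s] + (SL - i)
    rows <- (s - 1L) * SL + i
    coords[rows, 1] <- axis_pos * rise
    coords[rows, 2] <- ctr[s, 1]
    coords[rows, 3] <- ctr[s, 2]
  }
  if (jitter > 0) {
    set.seed(seed)
    noise <- matrix(stats::rnorm(length(coords), sd = jitter),
                    nrow = nrow(coords))
    noise <- pmin(pmax(noise, -jitter), jitter)
    coords <- coords + noise
  }
  list(frame = backbone_frame(coords),
       topology = system_topology(n_strands, SL),
       ground_truth = data.frame(p = seq_len(n_pairs),
                                 q = seq_len(n_pairs) + 1L,
                                 orientation = orientation,
                                 k = shift, stringsAsFactors = FALSE))
}

# place a rod of SL grains with center at `center` along unit vector `u`
rod_coords <- function(center, u, SL, rise = 3.4) {
  span <- (seq_len(SL) - (SL + 1) / 2) * rise
  sweep(outer(span, u), 2, center, "+")
}

#' Generate a random peptide gas
#'
#' Places `n_peptides` straight rods of `SL` grains with uniformly random
#' positions and orientations in a cubic box, enforcing a minimum
#' center-of-mass separation.  Deterministic under a fixed seed.
#'
#' @param n_peptides Number of peptides.
#' @param SL Grains per peptide.
#' @param box Cubic box edge length, Angstrom.
#' @param min_separation Minimum COM-COM distance, Angstrom (minimum image).
#' @param rise Grain spacing along each rod, Angstrom.
#' @param seed RNG seed.
#' @param max_tries Placement attempts per peptide before giving up.
#' @return List with `frame` (with box), `topology` and `centers`.
#' @export
make_random_gas <- function(n_peptides, SL, box, min_separation,
                            rise = 3.4, seed = 1L, max_tries = 2000L) {
  n_peptides <- as.integer(n_peptides); SL <- as.integer(SL)
  set.seed(seed)
  centers <- matrix(NA_real_, n_peptides, 3)
  boxv <- rep(box, 3)
  for (p in seq_len(n_peptides)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- stats::runif(3, 0, box)
      if (p == 1L) { ok <- TRUE } else {
        prev <- centers[seq_len(p - 1L), , drop = FALSE]
        dx <- sweep(prev, 2, cand)
        dx <- dx - sweep(round(sweep(dx, 2, boxv, "/")), 2, boxv, "*")
        ok <- all(sqrt(rowSums(dx^2)) >= min_separation)
      }
      if (ok) { centers[p, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place peptide ", p, " after ", max_tries,
           " tries; box too dense")
  }
  coords <- matrix(0, n_peptides * SL, 3)
  for (p in seq_len(n_peptides)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    coords[((p - 1L) * SL + 1L):(p * SL), ] <- rod_coords(centers[p, ], u, SL, rise)
  }
  list(frame = backbone_frame(coords, box = boxv),
       topology = system_topology(n_peptides, SL),
       centers = centers)
}

#' Generate a clustered aggregate with known components
#'
#' Builds one chain of peptide centers per cluster (adjacent centers at
#' `intra_com_distance`), with clusters separated by at least
#' `inter_cluster_distance`, so that distance-threshold component detection
#' with `intra < cutoff < inter` must recover exactly the designed
#' partition.  Peptides are short rods perpendicular to both the chain and
#' cluster-separation directions.
#'
#' @param cluster_sizes Integer vector of designed component sizes.
#' @param intra_com_distance COM spacing inside a cluster, Angstrom.
#' @param inter_cluster_distance Minimum distance between clusters, Angstrom.
#' @param SL Grains per peptide.
#' @param rise Grain spacing, Angstrom.
#' @param jitter Uniform positional noise half-width applied to peptide
#'   centers, Angstrom (kept < `intra_com_distance`/10 for guarantees).
#' @param seed RNG seed.
#' @return List with `frame`, `topology` and `ground_truth` (list of
#'   peptide-index vectors, the designed components).
#' @export
make_clustered_aggregate <- function(cluster_sizes, intra_com_distance = 10,
                                     inter_cluster_distance = 50,
                                     SL = 6L, rise = 3.4, jitter = 0.5,
                                     seed = 1L) {
  cluster_sizes <- as.integer(cluster_sizes)
  if (any(cluster_sizes < 1L)) stop("cluster sizes must be >= 1")
  if (intra_com_distance >= inter_cluster_distance)
    stop("need intra_com_distance < inter_cluster_distance")
  set.seed(seed)
  n_pep <- sum(cluster_sizes)
  centers <- matrix(0, n_pep, 3)
  truth <- vector("list", length(cluster_sizes))
  p <- 0L
  for (cl in seq_along(cluster_sizes)) {
    base_x <- (cl - 1L) * inter_cluster_distance * 1.5
    idx <- integer(cluster_sizes[cl])
    for (m in seq_len(cluster_sizes[cl])) {
      p <- p + 1L
      centers[p, ] <- c(base_x, (m - 1L) * intra_com_distance, 0)
      idx[m] <- p
    }
    truth[[cl]] <- idx
  }
  if (jitter > 0)
    centers <- centers + matrix(stats::runif(length(centers), -jitter, jitter),
                                nrow = n_pep)
  coords <- matrix(0, n_pep * SL, 3)
  for (q in seq_len(n_pep))
    coords[((q - 1L) * SL + 1L):(q * SL), ] <-
      rod_coords(centers[q, ], c(0, 0, 1), SL, rise)
  list(frame = backbone_frame(coords),
       topology = system_topology(n_pep, SL),
       ground_truth = truth)
}
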