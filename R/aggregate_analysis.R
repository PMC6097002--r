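# Aggregate-level analysis: oligomer identification by center-of-mass
# distance thresholding, nematic order parameter P2, radius of gyration.

#' Per-peptide centers of mass
#'
#' Unweighted mean of each peptide's backbone grain coordinates (only
#' backbone beads are guaranteed available at this coarsening level).
#'
#' @param frame A [backbone_frame].
#' @param topology A [system_topology] (strands = peptides).
#' @param strand_of Optional precomputed strand assignment.
#' @return Numeric `S x 3` matrix of centers, Angstrom.
#' @export
peptide_centers <- function(frame, topology, strand_of = NULL) {
  n <- nrow(frame$coords)
  if (is.null(strand_of))
    strand_of <- partition_strands(n, topology$n_strands,
                                   topology$strand_length,
                                   topology$chain_breaks)
  t(vapply(seq_len(topology$n_strands), function(s)
    colMeans(frame$coords[which(strand_of == s), , drop = FALSE]),
    numeric(3)))
}

#' Identify oligomers as distance-threshold connected components
#'
#' Two peptides are neighbours when their centers of mass are within
#' `cutoff` (default 11 Angstrom = 1.1 nm, the typical equatorial distance
#' of cross-beta structures in XRD spectra).  Oligomers are the connected
#' components of this neighbour graph; isolated peptides are reported
#' separately as singletons.
#'
#' @param centers `N x 3` matrix of peptide centers (from [peptide_centers]).
#' @param cutoff Neighbour distance threshold, Angstrom.
#' @param box Optional box lengths for minimum-image distances.
#' @param min_size Smallest component size reported as an oligomer
#'   (default 2).
#' @return Object of class `oligomer_set`: list with `components` (list of
#'   integer peptide-index vectors, size >= `min_size`, each sorted),
#'   `singletons`, `cutoff` and `n_peptides`.
#' @export
identify_oligomers <- function(centers, cutoff = 11.0, box = NULL,
                               min_size = 2L) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (n < 1L) stop("need at least one center")
  d <- pairwise_distances(centers, box)
  adj <- d <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(seq_len(n), comp$membership)
  sizes <- lengths(groups)
  components <- unname(lapply(groups[sizes >= max(2L, min_size)], sort))
  components <- components[order(vapply(components, min, integer(1)))]
  singletons <- sort(unlist(groups[sizes == 1L], use.names = FALSE))
  structure(list(components = components,
                 singletons = as.integer(singletons),
                 cutoff = cutoff, n_peptides = n),
            class = "oligomer_set")
}

#' @export
print.oligomer_set <- function(x, ...) {
  cat(sprintf("oligomer_set: %d peptide(s), %d oligomer(s), %d singleton(s) [cutoff %.1f A]\n",
              x$n_peptides, length(x$components), length(x$singletons),
              x$cutoff))
  if (length(x$components))
    cat("  sizes:", paste(lengths(x$components), collapse = ", "), "\n")
  invisible(x)
}

#' Nematic order parameter P2 of a peptide set
#'
#' Each peptide's molecular axis is the unit vector from its first to its
#' last backbone grain.  The orientational order tensor is
#' `Q = mean_m(3/2 u_m u_m' - 1/2 I)`; P2 is the largest eigenvalue of Q:
#' 1 for perfectly aligned axes (head-tail symmetric, so flipping any axis
#' changes nothing) and near 0 for an isotropic set.
#'
#' @param frame A [backbone_frame].
#' @param topology A [system_topology].
#' @param members Peptide (strand) indices; at least 2.
#' @param strand_of Optional precomputed strand assignment.
#' @return P2 in \[0, 1\] (clamped at 1e-9 tolerance).
#' @export
nematic_p2 <- function(frame, topology, members = seq_len(topology$n_strands),
                       strand_of = NULL) {
  n <- nrow(frame$coords)
  if (is.null(strand_of))
    strand_of <- partition_strands(n, topology$n_strands,
                                   topology$strand_length,
                                   topology$chain_breaks)
  if (length(members) < 2L) stop("P2 requires at least 2 peptides")
  axes <- t(vapply(members, function(m) {
    g <- which(strand_of == m)
    v <- frame$coords[g[length(g)], ] - frame$coords[g[1], ]
    nv <- sqrt(sum(v^2))
    if (nv <= 0) stop("peptide ", m, " has a zero-length axis")
    v / nv
  }, numeric(3)))
  p2_from_axes(axes)
}

# P2 from an N x 3 matrix of (not necessarily unit) axis vectors.
p2_from_axes <- function(axes) {
  axes <- axes / sqrt(rowSums(axes^2))
  q <- matrix(0, 3, 3)
  for (m in seq_len(nrow(axes)))
    q <- q + 1.5 * tcrossprod(axes[m, ]) - 0.5 * diag(3)
  q <- q / nrow(axes)
  p2 <- max(eigen(q, symmetric = TRUE, only.values = TRUE)$values)
  min(max(p2, 0), 1 + 1e-9)
}

#' Radius of gyration of a peptide set
#'
#' Root-mean-square distance of the member peptides' backbone grains from
#' their unweighted centroid.
#'
#' @param frame A [backbone_frame].
#' @param topology A [system_topology].
#' @param members Peptide (strand) indices (default: all).
#' @param strand_of Optional precomputed strand assignment.
#' @return R_g in Angstrom.
#' @export
radius_of_gyration <- function(frame, topology,
                               members = seq_len(topology$n_strands),
                               strand_of = NULL) {
  n <- nrow(frame$coords)
  if (is.null(strand_of))
    strand_of <- partition_strands(n, topology$n_strands,
                                   topology$strand_length,
                                   topology$chain_breaks)
  g <- which(strand_of %in% members)
  if (!length(g)) stop("no grains for the requested members")
  x <- frame$coords[g, , drop = FALSE]
  ctr <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2, ctr)^2)))
}

#' Per-oligomer order report
#'
#' Computes size, nematic P2 and radius of gyration for every oligomer of
#' an [identify_oligomers] result.
#'
#' @param frame A [backbone_frame].
#' @param topology A [system_topology].
#' @param oligomers An `oligomer_set`.
#' @return data.frame with columns id, size, p2, rg.
#' @export
order_report <- function(frame, topology, oligomers) {
  strand_of <- partition_strands(nrow(frame$coords), topology$n_strands,
                                 topology$strand_length,
                                 topology$chain_breaks)
  comps <- oligomers$components
  data.frame(
    id = seq_along(comps),
    size = if (length(comps)) lengths(comps) else integer(),
    p2 = vapply(comps, function(m)
      nematic_p2(frame, topology, m, strand_of = strand_of), numeric(1)),
    rg = vapply(comps, function(m)
      radius_of_gyration(frame, topology, m, strand_of = strand_of),
      numeric(1)))
}
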