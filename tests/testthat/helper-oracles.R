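# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the most naive formulation of each definition.

# all-pairs beta-contact matrix by explicit double loop; periodic distances
# by enumerating the 27 neighbouring images rather than the min-image formula
oracle_bb <- function(coords, strand_of, r_min = 4.7, r_max = 5.3,
                      box = NULL) {
  n <- nrow(coords)
  bb <- matrix(0L, n, n)
  shifts <- if (is.null(box)) matrix(0, 1, 3) else
    as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (is.na(strand_of[i]) || is.na(strand_of[j])) next
    if (strand_of[i] == strand_of[j]) next
    dmin <- Inf
    for (s in seq_len(nrow(shifts))) {
      delta <- coords[j, ] + (if (is.null(box)) 0 else shifts[s, ] * box) -
        coords[i, ]
      dmin <- min(dmin, sqrt(sum(delta^2)))
    }
    if (dmin >= r_min && dmin <= r_max) bb[i, j] <- 1L
  }
  bb
}

# exhaustive argmax over every template with explicit tie-break ordering
oracle_match <- function(sub, library, min_contacts = 3L) {
  if (sum(sub) == 0) return(NULL)
  rows <- lapply(library$templates, function(e) {
    ov <- sum(sub * e$template)
    data.frame(orientation = e$orientation, k = e$k,
               score = ov / sqrt(sum(sub) * sum(e$template)),
               contacts = ov, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$score, abs(tab$k),
                   tab$orientation != "parallel", tab$k < 0), ]
  best <- tab[1, ]
  # guard against float-order inversions among true ties
  ties <- tab[abs(tab$score - best$score) <= 1e-12, ]
  ties <- ties[order(abs(ties$k), ties$orientation != "parallel", ties$k < 0), ]
  best <- ties[1, ]
  if (best$contacts < min_contacts) return(NULL)
  list(orientation = best$orientation, k = as.integer(best$k),
       score = best$score, contacts = as.integer(best$contacts))
}

# connected components by hand-written breadth-first search
oracle_components <- function(centers, cutoff, box = NULL) {
  n <- nrow(centers)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    delta <- centers[j, ] - centers[i, ]
    if (!is.null(box)) delta <- delta - box * round(delta / box)
    if (sqrt(sum(delta^2)) <= cutoff) adj[i, j] <- TRUE
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (start in seq_len(n)) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, integer(1)))]
}

# canonical form for comparing component partitions
canon_components <- function(comps) {
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, integer(1)))]
}

# random rigid motion applied to a coordinate matrix
random_rigid_motion <- function(coords) {
  a <- stats::rnorm(3); a <- a / sqrt(sum(a^2))
  theta <- stats::runif(1, 0, 2 * pi)
  kmat <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3)
  rot <- diag(3) + sin(theta) * kmat + (1 - cos(theta)) * kmat %*% kmat
  sweep(coords %*% t(rot), 2, stats::rnorm(3, sd = 30), "+")
}

# minimal PDB text for synthetic test structures: one line per atom
pdb_atom_line <- function(serial, name, resname, chain, resno, xyz) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, name, resname, chain, resno, xyz[1], xyz[2], xyz[3])
}

# write a PDB of straight glycine strands whose backbone COMs reproduce the
# grain coordinates of an ideal-sheet fixture (atoms placed symmetrically
# around each designed grain position)
write_fixture_pdb <- function(frame, topology, path) {
  lines <- character()
  serial <- 0L
  n <- nrow(frame$coords)
  assign <- partition_strands(n, topology$n_strands, topology$strand_length,
                              topology$chain_breaks)
  chains <- c(LETTERS, letters, 0:9)
  w <- c(N = 14.007, CA = 12.011, C = 12.011, O = 15.999)
  for (g in seq_len(n)) {
    ctr <- frame$coords[g, ]
    # symmetric offsets with zero mass-weighted mean
    offs <- rbind(N = c(0.5, 0, 0), CA = c(-0.5, 0, 0),
                  C = c(0, 0.5, 0), O = c(0, -0.5, 0))
    offs <- sweep(offs, 2, colSums(offs * w) / sum(w))
    for (at in rownames(offs)) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, at, "GLY",
                                      chains[assign[g]],
                                      ((g - 1L) %% topology$strand_length) + 1L,
                                      ctr + offs[at, ]))
    }
    if (g %% topology$strand_length == 0L) lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  path
}
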