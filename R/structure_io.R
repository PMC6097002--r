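# Containers and readers for backbone-grain coordinate data.
#
# Internal length unit is Angstrom everywhere; GRO nm are converted on read.
# Indexing is R-native 1-based; user-facing reports are 1-based too.

#' System topology: strand partition of a backbone-grain sequence
#'
#' Describes how the linear sequence of backbone grains (one grain per
#' residue) is divided into `S` strands of `SL` grains each.  All analyses in
#' the package operate on this partition: the BB contact matrix is blocked by
#' strand, shift templates are `SL x SL`, and oligomer/peptide quantities are
#' per strand.
#'
#' @param n_strands Number of strands `S` (>= 1).
#' @param strand_length Backbone grains per strand `SL` (>= 3; the triplet
#'   heuristic and the template matching need at least three positions).
#' @param chain_breaks Integer vector of grain indices (1-based) that are the
#'   last grain of a chain; the strand partition never crosses a break.
#' @param labels Optional character vector of per-strand identifiers.
#' @return An object of class `system_topology`.
#' @export
system_topology <- function(n_strands, strand_length, chain_breaks = integer(),
                            labels = NULL) {
  n_strands <- as.integer(n_strands)
  strand_length <- as.integer(strand_length)
  if (is.na(n_strands) || n_strands < 1L)
    stop("n_strands must be an integer >= 1")
  if (is.na(strand_length) || strand_length < 3L)
    stop("strand_length must be an integer >= 3")
  if (!is.null(labels) && length(labels) != n_strands)
    stop("labels must have one entry per strand")
  structure(
    list(n_strands = n_strands,
         strand_length = strand_length,
         chain_breaks = sort(unique(as.integer(chain_breaks))),
         labels = labels %||% paste0("strand_", seq_len(n_strands))),
    class = "system_topology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.system_topology <- function(x, ...) {
  cat(sprintf("system_topology: S = %d strands x SL = %d grains (%d grains total)\n",
              x$n_strands, x$strand_length, x$n_strands * x$strand_length))
  if (length(x$chain_breaks))
    cat(sprintf("  chain breaks after grains: %s\n",
                paste(x$chain_breaks, collapse = ", ")))
  invisible(x)
}

#' Backbone coordinate frame
#'
#' One set of 3D backbone-grain positions, ordered by (strand, residue), with
#' optional orthorhombic box vectors (for minimum-image distances) and an
#' optional simulation time stamp.
#'
#' @param coords Numeric matrix `n x 3`, positions in Angstrom.
#' @param box Numeric length-3 vector of box edge lengths in Angstrom, or
#'   `NULL` for a non-periodic frame.
#' @param time Simulation time in ns, or `NA`.
#' @return An object of class `backbone_frame`.
#' @export
backbone_frame <- function(coords, box = NULL, time = NA_real_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  storage.mode(coords) <- "double"
  if (nrow(coords) < 1L) stop("frame contains no coordinates")
  if (any(!is.finite(coords))) stop("coords contain non-finite values")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be 3 positive edge lengths (Angstrom)")
  }
  structure(list(coords = coords, box = box, time = as.numeric(time)),
            class = "backbone_frame")
}

#' @export
print.backbone_frame <- function(x, ...) {
  cat(sprintf("backbone_frame: %d grains%s%s\n", nrow(x$coords),
              if (!is.null(x$box))
                sprintf(", box %.1f x %.1f x %.1f A", x$box[1], x$box[2], x$box[3])
              else ", no box",
              if (is.finite(x$time)) sprintf(", t = %g ns", x$time) else ""))
  invisible(x)
}

# Standard atomic masses for the backbone heavy atoms used in CG mapping.
.backbone_masses <- c(N = 14.007, CA = 12.011, C = 12.011, O = 15.999)

#' Load a PDB structure as backbone grains
#'
#' Maps each protein residue to a single backbone grain: either the
#' mass-weighted center of the backbone heavy atoms N, CA, C, O
#' (`"backbone_com"`, matching the MARTINI BB bead convention) or the CA
#' position (`"ca_only"`, a fallback for CA-trace entries).  Residues are
#' ordered by chain, then residue number.  Chain ends (and residue-numbering
#' gaps inside a chain, which indicate unresolved residues) are recorded as
#' chain breaks so that the strand partition never bridges them.
#'
#' @param path Path to a PDB file.
#' @param mapping `"backbone_com"` or `"ca_only"`.
#' @param model Model number to use for multi-model (NMR) entries; default 1.
#' @return A list with elements `frame` (a [backbone_frame], no box),
#'   `chain_breaks` (1-based indices of last grains of chains/segments) and
#'   `residues` (data.frame of chain, residue number, residue name per grain).
#' @export
load_pdb_backbone <- function(path, mapping = c("backbone_com", "ca_only"),
                              model = 1L) {
  mapping <- match.arg(mapping)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  # multi-model entries: substitute the requested model's coordinates
  # (bio3d's all-model xyz rows align column-triples with $atom rows)
  if (!is.null(pdb$xyz) && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1L) {
    if (model > nrow(pdb$xyz)) stop("model ", model, " not present in ", path)
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", path)
  atoms <- atoms[!duplicated(atoms[, c("chain", "resno", "insert", "elety")]), ,
                 drop = FALSE]

  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  key <- paste(atoms$chain, atoms$resno, ins, sep = "|")
  # preserve file order of residues (chains then residue number, as deposited)
  ukey <- unique(key)
  need <- if (mapping == "backbone_com") c("N", "CA", "C", "O") else "CA"

  coords <- matrix(NA_real_, nrow = length(ukey), ncol = 3L)
  res_chain <- character(length(ukey))
  res_no <- integer(length(ukey))
  res_name <- character(length(ukey))
  for (r in seq_along(ukey)) {
    rows <- atoms[key == ukey[r], , drop = FALSE]
    res_chain[r] <- rows$chain[1]
    res_no[r] <- rows$resno[1]
    res_name[r] <- rows$resid[1]
    sel <- match(need, rows$elety)
    if (anyNA(sel))
      stop(sprintf("residue %s %d (chain %s): missing backbone atom(s) %s",
                   rows$resid[1], rows$resno[1], rows$chain[1],
                   paste(need[is.na(sel)], collapse = ", ")))
    xyz <- as.matrix(rows[sel, c("x", "y", "z")])
    if (mapping == "backbone_com") {
      w <- .backbone_masses[need]
      coords[r, ] <- colSums(xyz * w) / sum(w)
    } else {
      coords[r, ] <- xyz[1, ]
    }
  }
  if (length(ukey) == 0L) stop("no residues mapped from ", path)

  # chain breaks: end of each chain, plus numbering gaps (unresolved residues)
  res_chain[is.na(res_chain)] <- ""
  breaks <- integer()
  for (r in seq_len(length(ukey) - 1L)) {
    if (res_chain[r + 1L] != res_chain[r] ||
        res_no[r + 1L] > res_no[r] + 1L)
      breaks <- c(breaks, r)
  }
  breaks <- c(breaks, length(ukey))

  list(frame = backbone_frame(coords),
       chain_breaks = breaks,
       residues = data.frame(chain = res_chain, resno = res_no,
                             resname = res_name, stringsAsFactors = FALSE))
}

#' Partition a grain sequence into strands
#'
#' Assigns grains consecutively to strands of length `SL`: strand `s` covers
#' grains `(s-1)*SL + 1 .. s*SL` within its chain segment.  The partition
#' restarts after every chain break; grains left over (fewer than `SL` at the
#' end of a segment, or beyond `S` strands) are flagged unassigned (`NA`) and
#' excluded from analysis.
#'
#' @param n_grains Total number of grains.
#' @param S Number of strands to form.
#' @param SL Grains per strand.
#' @param chain_breaks 1-based indices of last grains of chains.
#' @return Integer vector of length `n_grains`: strand index (1..S) or `NA`.
#' @export
partition_strands <- function(n_grains, S, SL, chain_breaks = integer()) {
  n_grains <- as.integer(n_grains); S <- as.integer(S); SL <- as.integer(SL)
  if (S * SL > n_grains)
    stop(sprintf("S x SL = %d exceeds the %d grains available", S * SL, n_grains))
  chain_breaks <- sort(unique(as.integer(chain_breaks)))
  chain_breaks <- chain_breaks[chain_breaks >= 1L & chain_breaks < n_grains]
  seg_start <- c(1L, chain_breaks + 1L)
  seg_end <- c(chain_breaks, n_grains)

  assign <- rep(NA_integer_, n_grains)
  s <- 0L
  for (g in seq_along(seg_start)) {
    at <- seg_start[g]
    while (s < S && at + SL - 1L <= seg_end[g]) {
      s <- s + 1L
      assign[at:(at + SL - 1L)] <- s
      at <- at + SL
    }
    if (s >= S) break
  }
  if (s < S)
    stop(sprintf(paste0("cannot form %d strands of length %d without crossing ",
                        "a chain break (only %d strands fit); offending strand: %d"),
         S, SL, s, s + 1L))
  assign
}

# --- GRO coordinate files -------------------------------------------------

#' Read a (possibly multi-frame) GRO file
#'
#' Parses the fixed-width GROMACS GRO format.  Coordinates are converted from
#' nm to Angstrom.  A frame time is taken from a `t=` token in the title line
#' when present (ps in GRO convention, converted to ns).
#'
#' @param path Path to a `.gro` file.
#' @return A list of frames; each frame is a list with `title`, `atom_name`,
#'   `res_name`, `res_id`, and a [backbone_frame] under `frame` holding all
#'   atoms in the file (selection happens in [load_cg_trajectory]).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("GRO file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms < 1L)
      stop("malformed GRO atom count at line ", i + 1L)
    if (i + 1L + natoms + 1L > length(lines))
      stop("truncated GRO frame starting at line ", i)
    al <- lines[(i + 2L):(i + 1L + natoms)]
    res_id <- as.integer(substr(al, 1L, 5L))
    res_name <- trimws(substr(al, 6L, 10L))
    atom_name <- trimws(substr(al, 11L, 15L))
    x <- as.numeric(substr(al, 21L, 28L))
    y <- as.numeric(substr(al, 29L, 36L))
    z <- as.numeric(substr(al, 37L, 44L))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop("malformed coordinates in GRO frame starting at line ", i)
    boxline <- as.numeric(strsplit(trimws(lines[i + 1L + natoms + 1L]),
                                   "\\s+")[[1]])
    box <- if (length(boxline) >= 3L && all(boxline[1:3] > 0))
      boxline[1:3] * 10 else NULL
    tm <- NA_real_
    m <- regmatches(title, regexec("t=\\s*([0-9.eE+-]+)", title))[[1]]
    if (length(m) == 2L) tm <- as.numeric(m[2]) / 1000  # ps -> ns
    frames[[length(frames) + 1L]] <-
      list(title = title, atom_name = atom_name, res_name = res_name,
           res_id = res_id,
           frame = backbone_frame(cbind(x, y, z) * 10, box = box, time = tm))
    i <- i + 1L + natoms + 2L
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

#' Write a backbone frame as a GRO file
#'
#' Writes one GRO frame (Angstrom converted back to nm, `%8.3f` precision, so
#' round-tripping is exact to 0.01 A).  Grains are written as `BB` beads, one
#' residue per grain; when `topology` is given, residue ids restart per strand
#' so that bead/strand structure is recoverable from the file.
#'
#' @param frame A [backbone_frame].
#' @param path Output path.
#' @param topology Optional [system_topology] used to label strands.
#' @param title Title line content.
#' @param append Append as an additional frame (multi-frame trajectory GRO).
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, topology = NULL, title = "strandscan frame",
                      append = FALSE) {
  n <- nrow(frame$coords)
  res_id <- seq_len(n)
  res_name <- rep("PEP", n)
  if (!is.null(topology)) {
    assign <- partition_strands(n, topology$n_strands, topology$strand_length,
                                topology$chain_breaks)
    res_id <- ifelse(is.na(assign), seq_len(n), assign)
  }
  if (is.finite(frame$time))
    title <- sprintf("%s t= %.4f", sub("\\s*t=.*$", "", title),
                     frame$time * 1000)
  nm <- frame$coords / 10
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     res_id %% 100000L, res_name, "BB", seq_len(n) %% 100000L,
                     nm[, 1], nm[, 2], nm[, 3]),
             if (!is.null(frame$box))
               sprintf("%10.5f%10.5f%10.5f", frame$box[1] / 10,
                       frame$box[2] / 10, frame$box[3] / 10)
             else sprintf("%10.5f%10.5f%10.5f", 0, 0, 0))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' Load a coarse-grained trajectory of backbone beads
#'
#' Reads a GRO topology (first frame defines the bead selection) and an
#' optional multi-frame GRO trajectory, keeping only beads whose atom name
#' matches `backbone_name` (default `"BB"`, the MARTINI backbone bead).
#' Coordinates are returned in Angstrom; per-frame box lengths are carried
#' through for minimum-image distance computation.
#'
#' @param topology_path GRO file defining beads (single frame used).
#' @param trajectory_path Optional multi-frame GRO trajectory; when `NULL`
#'   the topology frame itself is the single-frame trajectory.
#' @param backbone_name Bead-name selector.
#' @return List of [backbone_frame] objects, one per trajectory frame.
#' @export
load_cg_trajectory <- function(topology_path, trajectory_path = NULL,
                               backbone_name = "BB") {
  top <- read_gro(topology_path)[[1]]
  sel <- which(top$atom_name == backbone_name)
  if (!length(sel))
    stop("no beads named '", backbone_name, "' in ", topology_path)
  frames <- if (is.null(trajectory_path)) list(top)
            else read_gro(trajectory_path)
  lapply(frames, function(fr) {
    if (length(fr$atom_name) != length(top$atom_name))
      stop(sprintf("bead count mismatch: topology has %d, trajectory frame has %d",
                   length(top$atom_name), length(fr$atom_name)))
    backbone_frame(fr$frame$coords[sel, , drop = FALSE],
                   box = fr$frame$box, time = fr$frame$time)
  })
}
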