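#' Electron counts used as constant form factors
#'
#' At small angles the atomic form factor is treated as a Q-independent
#' constant equal to the element's electron count. Hydrogens can be ignored
#' (weight 0) to match the convention used for p(r).
#'
#' @param elements Character vector of element symbols.
#' @param ignore_hydrogens If `TRUE` (default), H gets weight 0.
#' @return Numeric vector of per-bead scattering weights (electrons).
#' @export
element_weights <- function(elements, ignore_hydrogens = TRUE) {
  tab <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)
  el <- toupper(trimws(elements))
  w <- tab[el]
  if (any(is.na(w)))
    abort(paste0("unknown element(s) with no explicit weight: ",
                 paste(unique(el[is.na(w)]), collapse = ", ")))
  if (ignore_hydrogens) w[el == "H"] <- 0
  unname(w)
}

#' Construct a bead structure
#'
#' A bead structure is one coordinate frame of a (coarse-grained or
#' atomistic) model: bead positions with per-bead constant scattering
#' weights, residue numbers and a backbone/other role label.
#'
#' @param coords Numeric matrix, n_beads x 3, in Angstrom.
#' @param weight Per-bead scattering weight (electrons), non-negative.
#' @param residue Per-bead residue number (integer).
#' @param role Per-bead role, `"backbone"` or `"other"`.
#' @return A tibble of class `bead_structure` with columns `x`, `y`, `z`,
#'   `weight`, `residue`, `role`.
#' @export
bead_structure <- function(coords, weight, residue = seq_len(nrow(coords)),
                           role = "backbone") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) abort("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (n < 1) abort("a structure needs at least one bead")
  weight <- rep_len(as.numeric(weight), n)
  residue <- rep_len(as.integer(residue), n)
  role <- rep_len(as.character(role), n)
  if (length(weight) != n || any(!is.finite(weight)) || any(weight < 0))
    abort("weights must be finite and non-negative")
  if (!all(role %in% c("backbone", "other")))
    abort("role must be 'backbone' or 'other'")
  out <- tibble(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                weight = weight, residue = residue, role = role)
  class(out) <- c("bead_structure", class(out))
  out
}

coords_matrix <- function(structure) {
  cbind(structure$x, structure$y, structure$z)
}

#' Construct a trajectory container
#'
#' A trajectory is an ordered sequence of frames sharing one topology
#' (bead count, weights, residue numbers, roles), stored as an
#' n_beads x 3 x n_frames array, plus the interval between stored
#' snapshots in nanoseconds per frame.
#'
#' @param coords Numeric array n_beads x 3 x n_frames.
#' @param topology Tibble with per-bead columns `weight`, `residue`, `role`
#'   (and optionally `atom`).
#' @param frame_interval Time between snapshots, ns/frame (default 2).
#' @return An object of class `sasclip_trajectory`.
#' @export
trajectory <- function(coords, topology, frame_interval = 2) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    abort("coords must be an n_beads x 3 x n_frames array")
  if (dim(coords)[3] < 1) abort("a trajectory needs at least one frame")
  if (frame_interval <= 0) abort("frame_interval must be positive")
  if (nrow(topology) != dim(coords)[1])
    abort("topology rows must match bead count")
  stopifnot(all(c("weight", "residue", "role") %in% names(topology)))
  structure(list(coords = coords, topology = as_tibble(topology),
                 frame_interval = frame_interval),
            class = "sasclip_trajectory")
}

#' @export
print.sasclip_trajectory <- function(x, ...) {
  cat(sprintf("<sasclip_trajectory: %d frames x %d beads, %g ns/frame>\n",
              n_frames(x), n_beads(x), x$frame_interval))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `sasclip_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Number of beads in a trajectory
#' @param traj A `sasclip_trajectory`.
#' @export
n_beads <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory as a bead structure
#'
#' @param traj A `sasclip_trajectory`.
#' @param i Frame index, 0-based (frame 0 is the first stored snapshot).
#' @export
get_frame <- function(traj, i) {
  if (i < 0 || i >= n_frames(traj)) abort("frame index out of range")
  bead_structure(traj$coords[, , i + 1, drop = TRUE],
                 weight = traj$topology$weight,
                 residue = traj$topology$residue,
                 role = traj$topology$role)
}

#' @export
tidy.sasclip_trajectory <- function(x, ...) {
  nb <- n_beads(x); nf <- n_frames(x)
  tibble(frame = rep(0:(nf - 1), each = nb),
         bead = rep(seq_len(nb), nf),
         x = as.vector(x$coords[, 1, ]),
         y = as.vector(x$coords[, 2, ]),
         z = as.vector(x$coords[, 3, ]),
         residue = rep(x$topology$residue, nf),
         role = rep(x$topology$role, nf))
}

#' Read a multi-frame trajectory
#'
#' Supported formats:
#' \describe{
#'   \item{`"pdb"`}{Multi-model PDB (one MODEL per frame), read with
#'     \pkg{bio3d}. Scattering weights are electron counts derived from the
#'     element column; beads whose atom name is in `backbone_atoms` get role
#'     `"backbone"`.}
#'   \item{`"xyz"`}{Concatenated XYZ blocks (`n`, comment, then `n` lines of
#'     `element x y z`). Residue numbers default to the bead index.}
#'   \item{`"frames"`}{A documented tabular format: whitespace-separated
#'     columns `frame x y z weight residue role`, `#` comments. Weights are
#'     taken verbatim; frames must share a topology.}
#' }
#'
#' @param path Input file.
#' @param format One of `"auto"`, `"pdb"`, `"xyz"`, `"frames"`. `"auto"`
#'   picks by file extension.
#' @param frame_interval ns per stored snapshot (default 2).
#' @param ignore_hydrogens Give hydrogens weight 0 (default `TRUE`).
#' @param backbone_atoms Atom names labelled as backbone beads
#'   (default `c("CA", "BB")`, covering C-alpha and coarse-grained
#'   backbone beads).
#' @return A `sasclip_trajectory`.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz", "frames"),
                            frame_interval = 2, ignore_hydrogens = TRUE,
                            backbone_atoms = c("CA", "BB")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", xyz = "xyz", "frames")
  }
  switch(format,
         pdb = read_trajectory_pdb(path, frame_interval, ignore_hydrogens,
                                   backbone_atoms),
         xyz = read_trajectory_xyz(path, frame_interval, ignore_hydrogens),
         frames = read_trajectory_frames(path, frame_interval))
}

read_trajectory_pdb <- function(path, frame_interval, ignore_hydrogens,
                                backbone_atoms) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                       # n_frames x 3*n_beads
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nb <- ncol(xyz) / 3
  nf <- nrow(xyz)
  elements <- pdb$atom$elesy
  if (is.null(elements) || all(is.na(elements)) || all(elements == ""))
    elements <- substr(trimws(pdb$atom$elety), 1, 1)
  w <- element_weights(elements, ignore_hydrogens)
  role <- ifelse(trimws(pdb$atom$elety) %in% backbone_atoms, "backbone", "other")
  coords <- array(0, dim = c(nb, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  topo <- tibble(atom = trimws(pdb$atom$elety), weight = w,
                 residue = as.integer(pdb$atom$resno), role = role)
  trajectory(coords, topo, frame_interval)
}

read_trajectory_xyz <- function(path, frame_interval, ignore_hydrogens) {
  lines <- readLines(path, warn = FALSE)
  i <- 1; frames <- list(); els <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) abort("malformed XYZ: expected an atom count line")
    if (i + 1 + n > length(lines)) abort("malformed XYZ: truncated frame")
    block <- lines[(i + 2):(i + 1 + n)]
    fields <- strsplit(trimws(block), "\\s+")
    el <- vapply(fields, `[[`, character(1), 1)
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (is.null(els)) els <- el
    else if (length(el) != length(els) || any(el != els))
      abort("frame topology mismatch across XYZ frames")
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  if (length(frames) == 0) abort("no frames in XYZ file")
  coords <- aperm(array(unlist(lapply(frames, t)),
                        dim = c(3, nrow(frames[[1]]), length(frames))),
                  c(2, 1, 3))
  topo <- tibble(atom = els,
                 weight = element_weights(els, ignore_hydrogens),
                 residue = seq_along(els), role = "backbone")
  trajectory(coords, topo, frame_interval)
}

read_trajectory_frames <- function(path, frame_interval) {
  tab <- read.table(path, header = TRUE, comment.char = "#")
  need <- c("frame", "x", "y", "z", "weight")
  if (!all(need %in% names(tab)))
    abort("frames format needs columns: frame x y z weight [residue role]")
  if (!"residue" %in% names(tab)) tab$residue <- NA
  if (!"role" %in% names(tab)) tab$role <- "backbone"
  ids <- sort(unique(tab$frame))
  per <- split(tab, factor(tab$frame, levels = ids))
  nb <- nrow(per[[1]])
  if (!all(vapply(per, nrow, integer(1)) == nb))
    abort("frame topology mismatch: differing bead counts across frames")
  first <- per[[1]]
  if (any(is.na(first$residue))) first$residue <- seq_len(nb)
  coords <- array(0, dim = c(nb, 3, length(per)))
  for (f in seq_along(per))
    coords[, , f] <- as.matrix(per[[f]][, c("x", "y", "z")])
  topo <- tibble(weight = first$weight, residue = as.integer(first$residue),
                 role = as.character(first$role))
  trajectory(coords, topo, frame_interval)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; beads are written as CA atoms of
#' residue type GLY unless the topology carries an `atom` column.
#'
#' @param traj A `sasclip_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  nb <- n_beads(traj); nf <- n_frames(traj)
  atom <- if ("atom" %in% names(traj$topology)) traj$topology$atom else rep("CA", nb)
  element <- if ("element" %in% names(traj$topology)) traj$topology$element
             else rep("C", nb)
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[, , f, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    writeLines(sprintf(
      "ATOM  %5d %-4s GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nb), substr(atom, 1, 4), traj$topology$residue,
      xyz[, 1], xyz[, 2], xyz[, 3], substr(element, 1, 2)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Define a named domain as an inclusive residue range
#'
#' @param name Domain label (e.g. `"a"`, `"b"`, `"bp"`, `"ap"`).
#' @param first_residue,last_residue Inclusive residue range.
#' @return One-row tibble with columns `name`, `first_residue`,
#'   `last_residue`.
#' @export
domain_def <- function(name, first_residue, last_residue) {
  if (first_residue > last_residue)
    abort("first_residue must be <= last_residue")
  tibble(name = as.character(name),
         first_residue = as.integer(first_residue),
         last_residue = as.integer(last_residue))
}

#' Three-domain preset for an ER-60-like protein disulfide isomerase fold
#'
#' Pfam-style ranges: a = 26-130, b-b' = 160-355, a' = 377-482. Four-domain
#' analyses additionally need the (user-supplied) boundary residue splitting
#' b from b'.
#'
#' @param bb_split If given, the last residue of the b domain; b' then runs
#'   from `bb_split + 1` to 355 and a four-domain table is returned.
#' @return A tibble of domain definitions.
#' @export
er60_domains <- function(bb_split = NULL) {
  if (is.null(bb_split)) {
    bind_rows(domain_def("a", 26, 130),
              domain_def("bb", 160, 355),
              domain_def("ap", 377, 482))
  } else {
    bind_rows(domain_def("a", 26, 130),
              domain_def("b", 160, bb_split),
              domain_def("bp", bb_split + 1, 355),
              domain_def("ap", 377, 482))
  }
}

#' Read a YAML analysis configuration
#'
#' Recognized top-level keys: `domains` (name -> `[first, last]` residue
#' ranges), `motifs` (name -> vector of residues), `criteria`
#' (`chi2_max`, `resid_max`, `resid_q_max`, `min_duration`,
#' `use_residual_band`), `bin_width` (degrees, for probability maps) and
#' `frame_interval` (ns/frame).
#'
#' @param path YAML file.
#' @return A list with elements `domains` (tibble), `motifs` (named list),
#'   `criteria` ([clip_criteria]), `bin_width`, `frame_interval`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  cfg <- yaml::read_yaml(path)
  domains <- NULL
  if (!is.null(cfg$domains)) {
    domains <- bind_rows(lapply(names(cfg$domains), function(nm) {
      r <- cfg$domains[[nm]]
      domain_def(nm, r[[1]], r[[2]])
    }))
  }
  crit <- do.call(clip_criteria, as.list(cfg$criteria %||% list()))
  list(domains = domains,
       motifs = cfg$motifs,
       criteria = crit,
       bin_width = cfg$bin_width %||% 5,
       frame_interval = cfg$frame_interval %||% 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
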