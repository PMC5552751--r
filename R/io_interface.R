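# Readers/writers for the text formats touched (multi-frame XYZ, PDB Calpha
# extraction, COLVAR/HILLS-style TSV, JSON configs) and the command-line
# entry point.

role_elements <- c(ligand = "C", protein = "O", anchor = "Fe")

#' Write conformations as multi-frame XYZ
#'
#' @param confs list of conformations (or a single one).
#' @param path output file.
#' @param system optional `egress_system`; element symbols are then taken
#'   from atom roles (ligand C, protein O, anchor Fe), else all atoms are
#'   written as C.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(confs, path, system = NULL) {
  if (inherits(confs, "egress_conformation")) confs <- list(confs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in confs) {
    x <- node_coords(cf)
    if (ncol(x) < 3) x <- cbind(x, matrix(0, nrow(x), 3 - ncol(x)))
    el <- if (!is.null(system)) role_elements[system$atoms$role] else rep("C", nrow(x))
    tm <- if (inherits(cf, "egress_conformation")) cf$time else 0
    lb <- if (inherits(cf, "egress_conformation")) cf$label else ""
    writeLines(c(sprintf("%d", nrow(x)),
                 sprintf("t= %.6f %s", tm %||% 0, lb)), con)
    writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", el, x[, 1], x[, 2], x[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path input file.
#' @return List of `egress_conformation`s (empty, with a warning, for an
#'   empty file). Malformed headers or atom-count mismatches raise a parse
#'   error naming the offending frame and line.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(length(lines))]
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    warning("empty XYZ file: ", path)
    return(list())
  }
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop(sprintf("XYZ parse error at line %d (frame %d): bad atom count '%s'",
                   i, frame, lines[i]), call. = FALSE)
    if (i + 1L + n > length(lines))
      stop(sprintf("XYZ parse error in frame %d: %d atoms declared at line %d but file ends early",
                   frame, n, i), call. = FALSE)
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad) > 0)
      stop(sprintf("XYZ parse error at line %d (frame %d): expected 'El x y z'",
                   i + 1L + bad[1], frame), call. = FALSE)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop(sprintf("XYZ parse error in frame %d: non-numeric coordinates", frame),
           call. = FALSE)
    tm <- 0
    m <- regmatches(comment, regexpr("t=\\s*[-0-9.eE+]+", comment))
    if (length(m) == 1) tm <- as.numeric(sub("t=\\s*", "", m))
    lb <- trimws(sub(".*t=\\s*[-0-9.eE+]+\\s*", "", comment))
    out[[frame]] <- conformation(xyz, time = tm, label = lb)
    i <- i + 2L + n
  }
  out
}

#' Extract Calpha coordinates from a PDB file
#'
#' Reads ATOM records (HETATM ignored unless `hetatm = TRUE`), keeps Calpha
#' atoms in file order, and resolves alternate locations by taking the first
#' (altLoc A).
#'
#' @param path PDB file.
#' @param hetatm also consider HETATM records.
#' @return An `egress_conformation` whose label lists the residues; residue
#'   identifiers in `attr(, "residues")`.
#' @export
read_pdb_calpha <- function(path, hetatm = FALSE) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (!hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0) stop("no Calpha atoms in ", path, call. = FALSE)
  key <- paste(at$chain, at$resno)
  at <- at[!duplicated(key), , drop = FALSE]   # first altLoc wins
  cf <- conformation(unname(as.matrix(at[, c("x", "y", "z")])),
                     label = sprintf("%d Calpha atoms", nrow(at)))
  attr(cf, "residues") <- paste0(at$resid, at$resno)
  cf
}

#' Write a COLVAR-style table
#'
#' Tab-separated, a single '#'-prefixed header naming the columns; fixed
#' column order time, s, sigma, z and optionally bias.
#'
#' @param rows tibble/data frame with columns `time`, `s`, `sigma`, `z` and
#'   optionally `bias`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_colvar <- function(rows, path) {
  cols <- c("time", "s", "sigma", "z")
  if ("bias" %in% names(rows)) cols <- c(cols, "bias")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(cols, collapse = "\t"),
                    "  (ps, -, -, A^2", if ("bias" %in% cols) ", kcal/mol", ")"), con)
  if (nrow(rows) > 0) {
    m <- as.matrix(as.data.frame(rows)[, cols])
    writeLines(apply(m, 1, function(r) paste(sprintf("%.9g", r), collapse = "\t")), con)
  }
  invisible(path)
}

#' Read a COLVAR-style table
#' @param path file written by [write_colvar()].
#' @return Tibble with the header's columns.
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]]
  hdr <- hdr[!grepl("[(),]", hdr)]
  body <- lines[-1]
  if (length(body) == 0)
    return(tibble::as_tibble(stats::setNames(rep(list(numeric()), length(hdr)), hdr)))
  m <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  colnames(m) <- hdr[seq_len(ncol(m))]
  tibble::as_tibble(m)
}

#' Write a HILLS-style table of deposited Gaussians
#' @param kernels tibble with `time`, `center`, `width`, `height` (an
#'   `egress_bias` is also accepted).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_hills <- function(kernels, path) {
  if (inherits(kernels, "egress_bias")) kernels <- kernels$kernels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time\tcenter\twidth\theight  (ps, CV, CV, kcal/mol)", con)
  if (nrow(kernels) > 0) {
    m <- as.matrix(as.data.frame(kernels)[, c("time", "center", "width", "height")])
    writeLines(apply(m, 1, function(r) paste(sprintf("%.12g", r), collapse = "\t")), con)
  }
  invisible(path)
}

#' Read a HILLS-style table
#' @param path file written by [write_hills()].
#' @return Tibble with columns `time`, `center`, `width`, `height`.
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0)
    return(tibble::tibble(time = numeric(), center = numeric(),
                          width = numeric(), height = numeric()))
  m <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  colnames(m) <- c("time", "center", "width", "height")
  tibble::as_tibble(m)
}

#' Write / read a path (multi-frame XYZ plus JSON sidecar)
#'
#' The sidecar (same name, `.json` extension) stores lambda, the 0-based
#' alignment/displacement atom indices, per-node MSDs and the completeness
#' flag.
#'
#' @param path an `egress_path`.
#' @param file output XYZ file; the sidecar replaces its extension by `.json`.
#' @param system optional system for element symbols.
#' @return Invisibly, `file`.
#' @export
write_path_xyz <- function(path, file, system = NULL) {
  write_xyz(path$nodes, file, system = system)
  side <- sub("\\.[^.]*$", ".json", file)
  jsonlite::write_json(list(
    lambda = path$lambda,
    lambda_override = isTRUE(path$lambda_override),
    alignment_set = path$alignment_set - 1L,
    displacement_set = path$displacement_set - 1L,
    neighbor_msd = path$neighbor_msd,
    mean_neighbor_msd = path$mean_neighbor_msd,
    complete = isTRUE(path$complete)
  ), side, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_path_xyz
#' @export
read_path_xyz <- function(file) {
  side <- sub("\\.[^.]*$", ".json", file)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  nodes <- read_xyz(file)
  new_path(nodes,
           alignment_set = meta$alignment_set + 1L,
           displacement_set = meta$displacement_set + 1L,
           lambda = if (isTRUE(meta$lambda_override)) meta$lambda else NULL,
           complete = isTRUE(meta$complete))
}

# ---- system / run-config JSON ----------------------------------------------

#' Serialize a system to JSON / read it back
#'
#' Atom table, restraints (0-based atom ids) and analytic parameters in a
#' documented JSON layout; initial coordinates included.
#'
#' @param system an `egress_system`.
#' @param path JSON file.
#' @return `write_system`: invisibly `path`; `read_system`: the system.
#' @export
write_system <- function(system, path) {
  rs <- lapply(system$restraints, function(r) {
    r2 <- r
    if (is.matrix(r2$reference)) r2$reference <- apply(r2$reference, 1, c, simplify = FALSE)
    r2
  })
  jsonlite::write_json(list(
    potential_kind = system$potential_kind,
    atoms = system$atoms,
    analytic_params = system$analytic_params,
    restraints = rs,
    dielectric = system$dielectric,
    coords0 = apply(system$coords0, 1, c, simplify = FALSE),
    cage = if (!is.null(system$cage)) list(
      center = system$cage$center, radius = system$cage$radius,
      tunnel_axes = apply(system$cage$tunnel_axes, 1, c, simplify = FALSE),
      tunnel_halfwidth = system$cage$tunnel_halfwidth) else NULL
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_system
#' @export
read_system <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  atoms <- tibble::as_tibble(j$atoms)
  atoms$id <- as.integer(atoms$id)
  rs <- list()
  if (length(j$restraints) > 0) {
    rs <- lapply(seq_len(if (is.data.frame(j$restraints)) nrow(j$restraints)
                         else length(j$restraints)),
                 function(i) {
      r <- if (is.data.frame(j$restraints)) as.list(j$restraints[i, ]) else j$restraints[[i]]
      r$targets <- as.integer(unlist(r$targets))
      if (!is.null(r$reference)) r$reference <- as_row_matrix(r$reference)
      if (is.list(r$center)) r$center <- unlist(r$center)
      r
    })
  }
  coords0 <- as_row_matrix(j$coords0)
  cage <- NULL
  if (!is.null(j$cage))
    cage <- list(center = unlist(j$cage$center), radius = j$cage$radius,
                 tunnel_axes = as_row_matrix(j$cage$tunnel_axes),
                 tunnel_halfwidth = j$cage$tunnel_halfwidth)
  new_system(atoms, j$potential_kind,
             analytic_params = as.list(j$analytic_params),
             restraints = rs, dielectric = j$dielectric %||% 1,
             coords0 = coords0, cage = cage)
}

# jsonlite may deliver a list of rows or an already-simplified matrix
as_row_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x)) return(do.call(rbind, lapply(x, unlist)))
  if (is.numeric(x) && length(x) > 1) return(matrix(x, 1))
  x
}

.config_blocks <- c("system", "dynamics", "pathsearch", "metad", "cluster")

#' Read and validate a run configuration
#'
#' JSON with blocks `system` (fixture parameters or an input file),
#' `dynamics` (T, friction, dt, steps, seed), `pathsearch`, `metad`,
#' `cluster`. Unknown top-level keys are rejected; basic physical ranges are
#' checked.
#'
#' @param path JSON file.
#' @return Named list of validated blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), .config_blocks)
  if (length(unknown) > 0)
    stop("unknown config block(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  dyn <- cfg$dynamics %||% list()
  if (!is.null(dyn$temperature) && dyn$temperature <= 0)
    stop("dynamics.temperature must be > 0", call. = FALSE)
  if (!is.null(dyn$dt) && (dyn$dt <= 0 || dyn$dt > 0.05))
    stop("dynamics.dt must be in (0, 0.05] ps", call. = FALSE)
  if (!is.null(cfg$metad$delta_t) && cfg$metad$delta_t <= 0)
    stop("metad.delta_t must be > 0", call. = FALSE)
  cfg
}

build_system_from_config <- function(cfg) {
  sb <- cfg$system %||% list()
  if (!is.null(sb$file)) return(read_system(sb$file))
  type <- sb$type %||% "cage"
  if (type == "cage") {
    make_cage_ligand(sb$n_cage %||% 60, sb$cage_radius %||% 10,
                     sb$n_tunnels %||% 3, sb$seed %||% 1,
                     tunnel_halfwidth = sb$tunnel_halfwidth %||% 25)
  } else if (type == "doublewell") {
    make_double_well(sb$barrier %||% 4, sb$spacing %||% 1, mass = sb$mass %||% 1)
  } else stop("unknown system type: ", type, call. = FALSE)
}
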