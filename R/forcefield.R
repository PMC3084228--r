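# Force-field parameter file (JSON) and system parameterization.

.defaultGlobals <- function()
  list(eps_in = 1.0, eps_out = 78.5, gamma = 0.0072, coulomb = 332.0636,
       probe = 1.4, temperature = 298, scale14_vdw = 0.5,
       scale14_elec = 1 / 1.2)

#' Element-level intrinsic generalized-Born radii
#'
#' An mbondi2-style per-element table (Angstrom) with matching screening
#' factors, used to fill in GB parameters for types that omit them.
#'
#' @return data.frame: element, radius, screen.
#' @export
mbondi2Radii <- function()
  data.frame(element = c("H", "C", "N", "O", "S", "P", "F", "CL", "BR"),
             radius = c(1.30, 1.70, 1.55, 1.50, 1.80, 1.85, 1.50, 1.70, 1.85),
             screen = c(0.85, 0.72, 0.79, 0.85, 0.96, 0.86, 0.88, 0.80, 0.80),
             stringsAsFactors = FALSE)

.MANDATORY_TYPE_FIELDS <- c("charge", "eps", "rmin2", "mass")

#' Load a force-field parameter file
#'
#' JSON schema: \code{types} (per atom type: charge, eps, rmin2, mass, and
#' optionally gb_radius, gb_screen, lcpo (P1..P4), lcpo_radius, element),
#' \code{globals} (defaults applied for missing entries only),
#' \code{atom_types} (atom name to type key) and optional \code{topology}
#' (\code{bonds} [i, j, k, r0], \code{angles} [i, j, k, ktheta, theta0],
#' \code{torsions} [i, j, k, l, vn, n, phase]; 1-based atom indices).
#' GB parameters missing from a type are filled from
#' \code{\link{mbondi2Radii}} via the type's element.
#'
#' @param file path to the JSON parameter file.
#' @return ForceFieldSpec.
#' @export
loadForcefield <- function(file) {
  raw <- jsonlite::fromJSON(file, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (is.null(raw$types) || !length(raw$types))
    stop("parameter schema error: missing 'types' section")
  mb <- mbondi2Radii()
  types <- lapply(names(raw$types), function(tn) {
    tp <- raw$types[[tn]]
    for (f in .MANDATORY_TYPE_FIELDS)
      if (is.null(tp[[f]]))
        stop(sprintf("parameter schema error: type '%s' is missing field '%s'",
                     tn, f))
    el <- toupper(tp$element %||% substr(tn, 1, 1))
    row <- match(el, mb$element)
    if (is.null(tp$gb_radius))
      tp$gb_radius <- if (!is.na(row)) mb$radius[row] else
        stop(sprintf("type '%s': no gb_radius and unknown element '%s'", tn, el))
    if (is.null(tp$gb_screen))
      tp$gb_screen <- if (!is.na(row)) mb$screen[row] else 0.8
    if (is.null(tp$lcpo)) tp$lcpo <- c(1, 0, 0, 0)
    if (is.null(tp$lcpo_radius)) tp$lcpo_radius <- tp$gb_radius
    if (tp$gb_radius <= 0 || tp$rmin2 <= 0 || tp$lcpo_radius <= 0)
      stop(sprintf("parameter schema error: type '%s' has a non-positive radius", tn))
    if (tp$mass <= 0)
      stop(sprintf("parameter schema error: type '%s' has a non-positive mass", tn))
    tp[c("charge", "eps", "rmin2", "mass", "gb_radius", "gb_screen",
         "lcpo", "lcpo_radius")]
  })
  names(types) <- names(raw$types)
  globals <- utils::modifyList(.defaultGlobals(), raw$globals %||% list())
  atomTypes <- unlist(raw$atom_types %||% character(0))
  topo <- raw$topology %||% list()
  asMat <- function(x, ncolHint) {
    if (is.null(x) || !length(x)) return(matrix(numeric(0), 0, ncolHint))
    m <- if (is.matrix(x)) x else do.call(rbind, x)
    storage.mode(m) <- "double"
    m
  }
  topology <- list(bonds = asMat(topo$bonds, 4),
                   angles = asMat(topo$angles, 5),
                   torsions = asMat(topo$torsions, 7))
  new("ForceFieldSpec", types = types, globals = globals,
      atomTypes = atomTypes, topology = topology)
}

#' Write a ForceFieldSpec as a JSON parameter file
#'
#' @param ff ForceFieldSpec.
#' @param path output file.
#' @export
writeForcefield <- function(ff, path) {
  out <- list(types = ff@types, globals = ff@globals,
              atom_types = as.list(ff@atomTypes),
              topology = lapply(ff@topology, function(m)
                if (is.null(m) || !nrow(m)) list() else unname(as.matrix(m))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a parameterized system from a complex and force field
#'
#' Resolves per-atom parameters through the force field's atom-name-to-type
#' map, takes bonded terms from the parameter file's topology, derives 1-2 and
#' 1-3 exclusions and scaled 1-4 pairs from the bond graph, and records the
#' receptor/ligand masks (single-trajectory convention: both subsystems are
#' sliced from complex coordinates).
#'
#' @param complex ComplexModel.
#' @param ff ForceFieldSpec with topology indexed against receptor atoms
#'   followed by ligand atoms.
#' @return ParameterizedSystem.
#' @export
parameterizeSystem <- function(complex, ff) {
  all <- rbind(complex@receptor@atoms, complex@ligand@atoms)
  nRec <- nrow(complex@receptor@atoms)
  ty <- ff@atomTypes[all$name]
  if (anyNA(ty))
    stop("parameterization error: no type for atom name(s) ",
         paste(unique(all$name[is.na(ty)]), collapse = ", "))
  bad <- setdiff(unique(ty), names(ff@types))
  if (length(bad))
    stop("parameterization error: unknown type(s) ", paste(bad, collapse = ", "))
  get <- function(field, k = 1L) {
    vals <- vapply(ty, function(t) ff@types[[t]][[field]][k], numeric(1))
    unname(vals)
  }
  atoms <- data.frame(
    name = all$name, element = all$element, chain = all$chain,
    resno = all$resno, resname = all$resname,
    charge = get("charge"), eps = get("eps"), rmin2 = get("rmin2"),
    mass = get("mass"), gb_radius = get("gb_radius"),
    gb_screen = get("gb_screen"),
    p1 = get("lcpo", 1L), p2 = get("lcpo", 2L), p3 = get("lcpo", 3L),
    p4 = get("lcpo", 4L), lcpo_radius = get("lcpo_radius"),
    is_h = toupper(all$element) == "H",
    subsystem = c(rep("receptor", nRec), rep("ligand", nrow(all) - nRec)),
    role = ifelse(seq_len(nrow(all)) > nRec, "ligand",
                  ifelse(all$name %in% c("N", "CA", "C", "O"),
                         "backbone", "sidechain")),
    stringsAsFactors = FALSE)
  n <- nrow(atoms)
  bonds <- ff@topology$bonds
  angles <- ff@topology$angles %||% matrix(numeric(0), 0, 5)
  torsions <- ff@topology$torsions %||% matrix(numeric(0), 0, 7)
  if (nrow(bonds) && max(bonds[, 1:2]) > n)
    stop("topology refers to atoms beyond the complex")
  # exclusions from the bond graph
  adj <- vector("list", n)
  if (nrow(bonds)) for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excl <- vector("list", n)
  p14 <- list()
  for (i in seq_len(n)) {
    one <- adj[[i]]
    two <- setdiff(unique(unlist(adj[one])), c(i, one))
    excl[[i]] <- as.integer(sort(unique(c(one, two, integer(0)))))
    three <- setdiff(unique(unlist(adj[two])), c(i, one, two))
    for (j in three[three > i]) p14[[length(p14) + 1L]] <- c(i, j)
  }
  pairs14 <- if (length(p14)) do.call(rbind, p14) else matrix(numeric(0), 0, 2)
  new("ParameterizedSystem", atoms = atoms, bonds = bonds, angles = angles,
      torsions = torsions, excl = excl, pairs14 = pairs14,
      globals = ff@globals)
}

#' Restrict a parameterized system to a subset of atoms
#'
#' Keeps the selected atoms and every bonded term fully inside the selection;
#' exclusions and 1-4 pairs are re-derived on the restricted bond graph.
#'
#' @param sys ParameterizedSystem.
#' @param idx integer atom indices to keep.
#' @return ParameterizedSystem.
#' @export
subsetSystem <- function(sys, idx) {
  idx <- sort(unique(as.integer(idx)))
  map <- integer(nrow(sys@atoms)); map[idx] <- seq_along(idx)
  keepTerm <- function(m, natoms) {
    if (!nrow(m)) return(m)
    inside <- rowSums(matrix(m[, seq_len(natoms)] %in% idx,
                             nrow = nrow(m))) == natoms
    m <- m[inside, , drop = FALSE]
    m[, seq_len(natoms)] <- map[m[, seq_len(natoms)]]
    m
  }
  bonds <- keepTerm(sys@bonds, 2L)
  angles <- keepTerm(sys@angles, 3L)
  torsions <- keepTerm(sys@torsions, 4L)
  n <- length(idx)
  adj <- vector("list", n)
  if (nrow(bonds)) for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excl <- vector("list", n)
  p14 <- list()
  for (i in seq_len(n)) {
    one <- adj[[i]]
    two <- setdiff(unique(unlist(adj[one])), c(i, one))
    excl[[i]] <- as.integer(sort(unique(c(one, two, integer(0)))))
    three <- setdiff(unique(unlist(adj[two])), c(i, one, two))
    for (j in three[three > i]) p14[[length(p14) + 1L]] <- c(i, j)
  }
  new("ParameterizedSystem", atoms = sys@atoms[idx, , drop = FALSE],
      bonds = bonds, angles = angles, torsions = torsions, excl = excl,
      pairs14 = if (length(p14)) do.call(rbind, p14) else
        matrix(numeric(0), 0, 2),
      globals = sys@globals)
}

#' Receptor / ligand atom indices of a system
#'
#' @param sys ParameterizedSystem.
#' @param which "receptor" or "ligand".
#' @export
subsystemIndices <- function(sys, which = c("receptor", "ligand")) {
  which <- match.arg(which)
  which(sys@atoms$subsystem == which)
}
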