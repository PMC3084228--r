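#' @import methods
NULL

.validAtomTable <- function(df) {
  need <- c("serial", "name", "element", "chain", "resno", "resname",
            "record", "x", "y", "z")
  if (!is.data.frame(df)) return("atoms must be a data.frame")
  miss <- setdiff(need, names(df))
  if (length(miss)) return(paste("missing atom columns:", paste(miss, collapse = ", ")))
  if (nrow(df) < 1L) return("a Structure must contain at least one atom")
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    return("all atomic coordinates must be finite")
  if (!all(df$record %in% c("protein", "hetero")))
    return("record must be 'protein' or 'hetero'")
  key <- paste(df$chain, df$resno, df$name)
  if (anyDuplicated(key))
    return("duplicated (chain, residue_number, atom name) within one model")
  TRUE
}

#' Atomic structure
#'
#' A single-model molecular structure: one row per atom with PDB-style
#' identity (serial, name, element, chain, residue number/name), a record
#' kind (\code{protein} for ATOM records, \code{hetero} for HETATM) and
#' Cartesian coordinates in Angstrom.
#'
#' @slot atoms data.frame with columns \code{serial, name, element, chain,
#'   resno, resname, record, x, y, z}.
#' @export
setClass("Structure", representation(atoms = "data.frame"),
         validity = function(object) .validAtomTable(object@atoms))

#' Receptor--ligand complex
#'
#' Partition of a structure into a receptor and a bound ligand (heavy atoms,
#' elements known). The two atom sets are disjoint.
#'
#' @slot receptor Structure.
#' @slot ligand Structure.
#' @export
setClass("ComplexModel",
         representation(receptor = "Structure", ligand = "Structure"),
         validity = function(object) {
           kr <- with(object@receptor@atoms, paste(chain, resno, name))
           kl <- with(object@ligand@atoms, paste(chain, resno, name))
           if (length(kl) < 1L) return("ligand must contain at least one atom")
           if (length(intersect(kr, kl)))
             return("receptor and ligand atom sets must be disjoint")
           TRUE
         })

#' Snapshot ensemble
#'
#' An ordered set of coordinate snapshots over a fixed atom roster, e.g.
#' frames extracted from a molecular-dynamics trajectory.
#'
#' @slot roster data.frame; the shared atom table (same columns as
#'   \code{Structure} minus coordinates, which live in \code{coords}).
#' @slot coords list of n_atoms x 3 numeric matrices, one per snapshot.
#' @slot times numeric, picoseconds, strictly increasing.
#' @export
setClass("TrajectoryEnsemble",
         representation(roster = "data.frame", coords = "list",
                        times = "numeric"),
         validity = function(object) {
           n <- nrow(object@roster)
           if (length(object@coords) < 1L) return("at least one snapshot required")
           ok <- vapply(object@coords, function(m)
             is.matrix(m) && nrow(m) == n && ncol(m) == 3L && all(is.finite(m)),
             logical(1))
           if (!all(ok)) return("every snapshot must be a finite n_atoms x 3 matrix")
           if (length(object@times) != length(object@coords))
             return("times and snapshots must have equal length")
           if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
           TRUE
         })

#' Geometric potential profile
#'
#' Per-residue burial scores on a C-alpha trace: a dimensionless geometric
#' potential (GP) in [0, 100] plus a unit environment direction (toward the
#' neighbour centroid; flagged absent for isolated residues).
#'
#' @slot profile data.frame with columns \code{chain, resno, resname, x, y, z,
#'   gp, dx, dy, dz, has_dir}.
#' @export
setClass("GeometricPotentialProfile", representation(profile = "data.frame"),
         validity = function(object) {
           p <- object@profile
           if (any(p$gp < -1e-9 | p$gp > 100 + 1e-9)) return("GP must lie in [0, 100]")
           nd <- sqrt(p$dx^2 + p$dy^2 + p$dz^2)[p$has_dir]
           if (length(nd) && any(abs(nd - 1) > 1e-6))
             return("environment directions must be unit vectors")
           TRUE
         })

#' Ligand binding site
#'
#' A set of receptor residues defining a binding site: residue identities
#' (ordered by residue number), C-alpha coordinates, attached GP scores and
#' the site centroid.
#'
#' @slot parentId character scalar identifying the parent structure.
#' @slot residues data.frame with columns \code{chain, resno, resname, gp}.
#' @slot caCoords numeric matrix (n x 3) of C-alpha coordinates.
#' @slot centroid numeric length-3.
#' @export
setClass("BindingSite",
         representation(parentId = "character", residues = "data.frame",
                        caCoords = "matrix", centroid = "numeric"),
         validity = function(object) {
           r <- object@residues
           if (nrow(r) != nrow(object@caCoords))
             return("residue table and caCoords must align")
           if (anyDuplicated(paste(r$chain, r$resno))) return("residue ids must be unique")
           if (nrow(r) > 1L && is.unsorted(order(r$chain, r$resno)[seq_len(0)])) TRUE
           TRUE
         })

#' Binding-site alignment result
#'
#' Residue correspondences between two sites, the similarity score, and the
#' rigid transform (proper rotation + translation) mapping site B onto site A
#' with the resulting paired C-alpha RMSD.
#'
#' @slot pairs data.frame with columns \code{idxA, idxB} (row indices into the
#'   two sites' residue tables).
#' @slot score numeric similarity score (sum of pair weights).
#' @slot rotation 3 x 3 proper rotation matrix.
#' @slot translation numeric length-3.
#' @slot rmsd numeric, Angstrom, over paired C-alpha after the transform.
#' @slot hasTransform logical; FALSE for empty alignments.
#' @export
setClass("AlignmentResult",
         representation(pairs = "data.frame", score = "numeric",
                        rotation = "matrix", translation = "numeric",
                        rmsd = "numeric", hasTransform = "logical"),
         validity = function(object) {
           p <- object@pairs
           if (nrow(p) && (anyDuplicated(p$idxA) || anyDuplicated(p$idxB)))
             return("pairs must be injective on both sides")
           if (object@hasTransform) {
             if (abs(det(object@rotation) - 1) > 1e-6)
               return("rotation must be proper (determinant +1)")
             if (object@rmsd < -1e-12) return("rmsd must be non-negative")
           }
           TRUE
         })

#' Gumbel (type-I extreme value) score model
#'
#' Location/scale model for best-of-many alignment scores, used to convert a
#' similarity score into a p-value.
#'
#' @slot mu numeric location (score units).
#' @slot beta numeric scale, strictly positive.
#' @export
setClass("EVDModel", representation(mu = "numeric", beta = "numeric"),
         validity = function(object)
           if (object@beta <= 0) "beta must be > 0" else TRUE)

#' Force-field specification
#'
#' Per-atom-type nonbonded, generalized-Born and LCPO parameters plus global
#' constants. Bonded terms and the atom-name-to-type map travel with the
#' parameter file (see \code{\link{loadForcefield}}).
#'
#' @slot types named list; per type: \code{charge} (e), \code{eps} (kcal/mol),
#'   \code{rmin2} (Angstrom, r_min/2), \code{mass} (amu), \code{gb_radius}
#'   (Angstrom), \code{gb_screen}, \code{lcpo} (P1..P4), \code{lcpo_radius}.
#' @slot globals list: \code{eps_in} (1.0), \code{eps_out} (78.5),
#'   \code{gamma} (0.0072 kcal/mol/A^2), \code{coulomb} (332.0636),
#'   \code{probe} (1.4 A), \code{temperature} (298 K).
#' @slot atomTypes named character; atom name -> type key.
#' @slot topology list with elements \code{bonds}, \code{angles},
#'   \code{torsions} (possibly empty), 1-based atom indices plus constants.
#' @export
setClass("ForceFieldSpec",
         representation(types = "list", globals = "list",
                        atomTypes = "character", topology = "list"),
         validity = function(object) {
           g <- object@globals
           if (g$eps_out <= g$eps_in || g$eps_in < 1)
             return("dielectrics must satisfy eps_out > eps_in >= 1")
           for (tn in names(object@types)) {
             tp <- object@types[[tn]]
             if (tp$eps < 0) return(sprintf("type %s: LJ well depth must be >= 0", tn))
             if (tp$mass <= 0) return(sprintf("type %s: mass must be > 0", tn))
             if (tp$gb_radius <= 0 || tp$rmin2 <= 0 || tp$lcpo_radius <= 0)
               return(sprintf("type %s: radii must be > 0", tn))
           }
           TRUE
         })

#' Parameterized molecular system
#'
#' Topology (bonds, angles, torsions, 1-2/1-3 exclusions, scaled 1-4 pairs)
#' with resolved per-atom parameters and receptor/ligand subsystem masks.
#'
#' @slot atoms data.frame: per-atom identity, resolved parameters
#'   (\code{charge, eps, rmin2, mass, gb_radius, gb_screen, p1..p4,
#'   lcpo_radius}), flags (\code{is_h}) and \code{subsystem}
#'   ("receptor"/"ligand") and \code{role} ("backbone"/"sidechain"/"ligand").
#' @slot bonds numeric matrix: i, j, k (kcal/mol/A^2), r0 (A).
#' @slot angles numeric matrix: i, j, k, ktheta (kcal/mol/rad^2), theta0 (rad).
#' @slot torsions numeric matrix: i, j, k, l, vn (kcal/mol), n, phase (rad).
#' @slot excl list of integer vectors: for each atom, the 1-2/1-3 partners.
#' @slot pairs14 numeric matrix: i, j pairs scaled by the 1-4 factors.
#' @slot globals list (see \code{ForceFieldSpec}).
#' @export
setClass("ParameterizedSystem",
         representation(atoms = "data.frame", bonds = "matrix",
                        angles = "matrix", torsions = "matrix",
                        excl = "list", pairs14 = "matrix", globals = "list"),
         validity = function(object) {
           a <- object@atoms
           if (!all(a$subsystem %in% c("receptor", "ligand")))
             return("subsystem mask must partition atoms into receptor/ligand")
           if (any(!is.finite(a$charge)) || any(a$mass <= 0))
             return("every atom must carry finite parameters and positive mass")
           TRUE
         })

#' Single-state MM/GBSA energy breakdown
#'
#' Gas-phase molecular-mechanics terms, solvation terms, and entropy terms for
#' one molecular state at one coordinate set. All values kcal/mol.
#'
#' @slot bond,angle,torsion,vdw,elec gas-phase terms; their sum is E_MM.
#' @slot gb polar (generalized-Born) solvation free energy.
#' @slot sa nonpolar solvation, gamma * SASA.
#' @slot tsTrans,tsRot,tsVib entropy terms as T*S.
#' @slot entropyComputed logical; FALSE when entropy was skipped (TS terms 0).
#' @export
setClass("EnergyBreakdown",
         representation(bond = "numeric", angle = "numeric", torsion = "numeric",
                        vdw = "numeric", elec = "numeric", gb = "numeric",
                        sa = "numeric", tsTrans = "numeric", tsRot = "numeric",
                        tsVib = "numeric", entropyComputed = "logical"))

#' Ensemble binding free energy
#'
#' Per-snapshot binding free-energy components and their ensemble means with
#' standard errors: dG = dH - dTS (kcal/mol).
#'
#' @slot perSnapshot data.frame: time, dEmm, dGgb, dGsa, dH, dTS, dG.
#' @slot dH,dTS,dG ensemble means (kcal/mol).
#' @slot seDH,seDTS,seDG standard errors of the means.
#' @slot n integer snapshot count.
#' @export
setClass("BindingFreeEnergy",
         representation(perSnapshot = "data.frame", dH = "numeric",
                        dTS = "numeric", dG = "numeric", seDH = "numeric",
                        seDTS = "numeric", seDG = "numeric", n = "integer"),
         validity = function(object) {
           if (object@n < 1L) return("snapshot count must be positive")
           if (abs(object@dG - (object@dH - object@dTS)) > 1e-9)
             return("dG must equal dH - dTS")
           TRUE
         })

.NODE_KINDS <- c("off_target", "intermediate", "pathway", "effect")
.EDGE_SIGNS <- c("activation", "inhibition", "dual")

#' Signed interaction network
#'
#' Typed nodes (off-target, intermediate protein, pathway, cellular effect)
#' joined by signed edges (activation, inhibition, or dual).
#'
#' @slot nodes data.frame: id, kind.
#' @slot edges data.frame: source, target, sign.
#' @export
setClass("SignedNetwork",
         representation(nodes = "data.frame", edges = "data.frame"),
         validity = function(object) {
           n <- object@nodes; e <- object@edges
           if (!all(n$kind %in% .NODE_KINDS)) return("unknown node kind")
           if (nrow(e)) {
             if (!all(e$sign %in% .EDGE_SIGNS)) return("unknown edge sign")
             if (!all(c(e$source, e$target) %in% n$id))
               return("edge endpoints must exist as nodes")
             if (any(e$source == e$target)) return("self-loops are not allowed")
           }
           if (anyDuplicated(n$id)) return("node ids must be unique")
           TRUE
         })

#' Signed perturbation result
#'
#' Qualitative per-node consequence of inhibiting a set of off-target nodes:
#' direction up/down/mixed/unchanged plus supporting signal counts.
#'
#' @slot directions data.frame: id, kind, direction, n_up, n_down.
#' @slot inhibited character; the perturbed off-target node ids.
#' @export
setClass("PerturbationResult",
         representation(directions = "data.frame", inhibited = "character"),
         validity = function(object) {
           d <- object@directions
           if (!all(d$direction %in% c("up", "down", "mixed", "unchanged")))
             return("direction must be up/down/mixed/unchanged")
           TRUE
         })
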