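#' Accessors
#'
#' Small accessor generics for the package's S4 containers. Slots are never
#' reached into directly by user code.
#'
#' @param x an offtargetr object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setMethod("atomTable", "Structure", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("atomTable", "TrajectoryEnsemble", function(x) x@roster)

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("nAtoms", "TrajectoryEnsemble", function(x) nrow(x@roster))

#' @rdname accessors
#' @export
setGeneric("coordMatrix", function(x, ...) standardGeneric("coordMatrix"))
#' @rdname accessors
#' @export
setMethod("coordMatrix", "Structure", function(x, ...)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))
#' @param i snapshot index.
#' @param ... unused.
#' @rdname accessors
#' @export
setMethod("coordMatrix", "TrajectoryEnsemble", function(x, i = 1L, ...) x@coords[[i]])

#' @rdname accessors
#' @export
setGeneric("snapshotTimes", function(x) standardGeneric("snapshotTimes"))
#' @rdname accessors
#' @export
setMethod("snapshotTimes", "TrajectoryEnsemble", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("nSnapshots", function(x) standardGeneric("nSnapshots"))
#' @rdname accessors
#' @export
setMethod("nSnapshots", "TrajectoryEnsemble", function(x) length(x@coords))

#' @rdname accessors
#' @export
setGeneric("receptor", function(x) standardGeneric("receptor"))
#' @rdname accessors
#' @export
setMethod("receptor", "ComplexModel", function(x) x@receptor)

#' @rdname accessors
#' @export
setGeneric("ligand", function(x) standardGeneric("ligand"))
#' @rdname accessors
#' @export
setMethod("ligand", "ComplexModel", function(x) x@ligand)

#' @rdname accessors
#' @export
setGeneric("gpProfile", function(x) standardGeneric("gpProfile"))
#' @rdname accessors
#' @export
setMethod("gpProfile", "GeometricPotentialProfile", function(x) x@profile)

#' @rdname accessors
#' @export
setGeneric("siteResidues", function(x) standardGeneric("siteResidues"))
#' @rdname accessors
#' @export
setMethod("siteResidues", "BindingSite", function(x) x@residues)

#' @rdname accessors
#' @export
setGeneric("siteCoords", function(x) standardGeneric("siteCoords"))
#' @rdname accessors
#' @export
setMethod("siteCoords", "BindingSite", function(x) x@caCoords)

#' @rdname accessors
#' @export
setGeneric("siteCentroid", function(x) standardGeneric("siteCentroid"))
#' @rdname accessors
#' @export
setMethod("siteCentroid", "BindingSite", function(x) x@centroid)

#' @rdname accessors
#' @export
setGeneric("parentId", function(x) standardGeneric("parentId"))
#' @rdname accessors
#' @export
setMethod("parentId", "BindingSite", function(x) x@parentId)

#' @rdname accessors
#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))
#' @rdname accessors
#' @export
setMethod("alignedPairs", "AlignmentResult", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @rdname accessors
#' @export
setMethod("alignmentScore", "AlignmentResult", function(x) x@score)

#' @rdname accessors
#' @export
setGeneric("alignmentTransform", function(x) standardGeneric("alignmentTransform"))
#' @rdname accessors
#' @export
setMethod("alignmentTransform", "AlignmentResult", function(x) {
  if (!x@hasTransform) stop("alignment is empty: no transform available")
  list(rotation = x@rotation, translation = x@translation)
})

#' @rdname accessors
#' @export
setGeneric("alignmentRmsd", function(x) standardGeneric("alignmentRmsd"))
#' @rdname accessors
#' @export
setMethod("alignmentRmsd", "AlignmentResult", function(x) x@rmsd)

#' @rdname accessors
#' @export
setGeneric("evdLocation", function(x) standardGeneric("evdLocation"))
#' @rdname accessors
#' @export
setMethod("evdLocation", "EVDModel", function(x) x@mu)

#' @rdname accessors
#' @export
setGeneric("evdScale", function(x) standardGeneric("evdScale"))
#' @rdname accessors
#' @export
setMethod("evdScale", "EVDModel", function(x) x@beta)

#' @rdname accessors
#' @export
setGeneric("energyTerms", function(x) standardGeneric("energyTerms"))
#' @rdname accessors
#' @export
setMethod("energyTerms", "EnergyBreakdown", function(x)
  c(bond = x@bond, angle = x@angle, torsion = x@torsion, vdw = x@vdw,
    elec = x@elec, gb = x@gb, sa = x@sa, ts_trans = x@tsTrans,
    ts_rot = x@tsRot, ts_vib = x@tsVib))

#' Gas-phase molecular-mechanics total E_MM
#' @param x an EnergyBreakdown.
#' @export
eMM <- function(x) x@bond + x@angle + x@torsion + x@vdw + x@elec

#' Total free energy E_MM + G_GB + G_SA - TS
#' @param x an EnergyBreakdown.
#' @export
gTotal <- function(x) eMM(x) + x@gb + x@sa - (x@tsTrans + x@tsRot + x@tsVib)

#' @rdname accessors
#' @export
setGeneric("bindingSummary", function(x) standardGeneric("bindingSummary"))
#' @rdname accessors
#' @export
setMethod("bindingSummary", "BindingFreeEnergy", function(x)
  data.frame(dH = x@dH, dTS = x@dTS, dG = x@dG, se_dH = x@seDH,
             se_dTS = x@seDTS, se_dG = x@seDG, n_snapshots = x@n))

#' @rdname accessors
#' @export
setGeneric("perSnapshotEnergies", function(x) standardGeneric("perSnapshotEnergies"))
#' @rdname accessors
#' @export
setMethod("perSnapshotEnergies", "BindingFreeEnergy", function(x) x@perSnapshot)

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setMethod("networkNodes", "SignedNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setMethod("networkEdges", "SignedNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("nodeDirections", function(x) standardGeneric("nodeDirections"))
#' @rdname accessors
#' @export
setMethod("nodeDirections", "PerturbationResult", function(x) x@directions)

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat(sprintf("Structure: %d atoms, %d residues, %d chain(s) [%d hetero atoms]\n",
              nrow(a), length(unique(paste(a$chain, a$resno))),
              length(unique(a$chain)), sum(a$record == "hetero")))
})

setMethod("show", "ComplexModel", function(object)
  cat(sprintf("ComplexModel: receptor %d atoms, ligand %d atoms (%s)\n",
              nAtoms(object@receptor), nAtoms(object@ligand),
              paste(unique(object@ligand@atoms$resname), collapse = ","))))

setMethod("show", "TrajectoryEnsemble", function(object)
  cat(sprintf("TrajectoryEnsemble: %d snapshots x %d atoms, t = %g..%g ps\n",
              nSnapshots(object), nAtoms(object),
              min(object@times), max(object@times))))

setMethod("show", "BindingSite", function(object)
  cat(sprintf("BindingSite on %s: %d residues\n", object@parentId,
              nrow(object@residues))))

setMethod("show", "AlignmentResult", function(object)
  cat(sprintf("AlignmentResult: %d pairs, score %.3f, rmsd %.3f A\n",
              nrow(object@pairs), object@score,
              if (object@hasTransform) object@rmsd else NA_real_)))

setMethod("show", "EVDModel", function(object)
  cat(sprintf("EVDModel (Gumbel): mu = %.4f, beta = %.4f\n",
              object@mu, object@beta)))

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf("EnergyBreakdown (kcal/mol): E_MM %.3f | G_GB %.3f | G_SA %.3f | TS %.3f\n",
              eMM(object), object@gb, object@sa,
              object@tsTrans + object@tsRot + object@tsVib))
})

setMethod("show", "BindingFreeEnergy", function(object)
  cat(sprintf("BindingFreeEnergy over %d snapshots: dH %.2f, dTS %.2f, dG %.2f kcal/mol\n",
              object@n, object@dH, object@dTS, object@dG)))

setMethod("show", "SignedNetwork", function(object)
  cat(sprintf("SignedNetwork: %d nodes (%s), %d edges\n",
              nrow(object@nodes),
              paste(sprintf("%d %s", tabulate(factor(object@nodes$kind, .NODE_KINDS),
                                              length(.NODE_KINDS)), .NODE_KINDS),
                    collapse = ", "),
              nrow(object@edges))))

setMethod("show", "PerturbationResult", function(object) {
  d <- object@directions
  cat(sprintf("PerturbationResult: inhibited {%s}; %d down, %d up, %d mixed, %d unchanged\n",
              paste(object@inhibited, collapse = ", "),
              sum(d$direction == "down"), sum(d$direction == "up"),
              sum(d$direction == "mixed"), sum(d$direction == "unchanged")))
})
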