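#' @describeIn buildCircularMesh number of mesh nodes
#' @param mesh a \linkS4class{DOTMesh}.
#' @export
nNodes <- function(mesh) nrow(mesh@nodes)

#' Node coordinates of a mesh
#' @param mesh a \linkS4class{DOTMesh}.
#' @return n x 2 matrix (mm).
#' @export
meshNodes <- function(mesh) mesh@nodes

#' Amplitude matrix of a measurement set
#' @param m a \linkS4class{MeasurementSet}.
#' @return 16 x 15 matrix.
#' @export
amplitude <- function(m) m@amplitude

#' Phase matrix of a measurement set
#' @param m a \linkS4class{MeasurementSet}.
#' @return 16 x 15 matrix (radians).
#' @export
phase <- function(m) m@phase

#' Property values of a PropertyImage
#' @param img a \linkS4class{PropertyImage}.
#' @return 64 x 64 x 2 array (1/mm).
#' @export
propertyValues <- function(img) img@values

#' Inside-disk mask of a PropertyImage
#' @param img a \linkS4class{PropertyImage}.
#' @return 64 x 64 logical matrix.
#' @export
domainMask <- function(img) img@mask

#' Speed of light in the medium
#' @param pc a \linkS4class{PhysicsConstants}.
#' @return mm/ns.
#' @export
lightSpeed <- function(pc) pc@lightSpeed

setMethod("show", "DOTMesh", function(object) {
  cat(sprintf("DOTMesh: %d nodes, %d triangles, radius %.1f mm, h ~ %.2f mm\n",
              nrow(object@nodes), nrow(object@triangles), object@radius,
              object@h))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf(
    "Phantom: d = %.1f mm, mu_a = %.4f, mu_s' = %.3f /mm, f = %.1f MHz, %d inclusion(s)\n",
    object@diameter, object@backgroundMuA, object@backgroundMuSp,
    object@frequency, length(object@inclusions)))
  for (inc in object@inclusions)
    cat(sprintf("  inclusion r = %.1f mm at (%.1f, %.1f), contrast a/s = %.2f/%.2f\n",
                inc@radius, inc@center[1], inc@center[2], inc@contrastA,
                inc@contrastS))
})

setMethod("show", "MeasurementSet", function(object) {
  cat(sprintf(
    "MeasurementSet: 16 x 15 amplitude/phase at %.1f MHz (amp %.3g..%.3g)\n",
    object@frequency, min(object@amplitude), max(object@amplitude)))
})

setMethod("show", "PropertyImage", function(object) {
  cat(sprintf(
    "PropertyImage: 64 x 64 x 2, pitch %.3f mm, mu_a %.4f..%.4f, mu_s' %.3f..%.3f /mm\n",
    object@pixelPitch, min(object@values[, , 1]), max(object@values[, , 1]),
    min(object@values[, , 2]), max(object@values[, , 2])))
})

setMethod("show", "DOTDataset", function(object) {
  cat(sprintf("DOTDataset: %d samples (%d train / %d val / %d test), seed %d\n",
              nSamples(object), sum(object@split == "train"),
              sum(object@split == "val"), sum(object@split == "test"),
              object@seed))
})

setMethod("show", "CAFNetModel", function(object) {
  cat(sprintf("CAFNetModel (%s): %d trainable parameters%s\n",
              object@config@variant, countParameters(object),
              if (length(object@history$train))
                sprintf(", trained %d epochs (final loss %.5f)",
                        length(object@history$train),
                        utils::tail(object@history$train, 1)) else ""))
})

setMethod("show", "ReconResult", function(object) {
  cat(sprintf(
    "ReconResult: %d iterations, residual %.4g -> %.4g%s\n",
    object@iterations, object@residualHistory[1],
    utils::tail(object@residualHistory, 1),
    if (object@diverged) " (diverged; best iterate returned)" else ""))
})
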