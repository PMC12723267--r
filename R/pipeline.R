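#' Desk-scale reproduction profile
#'
#' A single configuration bundle for the end-to-end pipeline at desk scale:
#' 600 phantoms (510/60/30 split), 24 training epochs at batch size 8 for
#' the headline network (batch 8 preserves the steps-per-epoch ratio of the
#' full-scale study, where batch 64 serves 8,500 training samples), 8-epoch
#' ablation trainings, simulation mesh diameter/25, and the Gauss-Newton
#' baseline on the first 20 test phantoms.  The full study conditions
#' (10,000 samples, 100 epochs, batch 64) are reachable by overriding `n`,
#' `epochs` and `batchSize`.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n number of phantoms.
#' @param epochs headline training epochs.
#' @param ablationEpochs epochs for the ablation variant comparison.
#' @param batchSize training minibatch size.
#' @return a named list understood by [runPipeline()].
#' @export
paperScaledProfile <- function(seed = 1, n = 600, epochs = 24,
                               ablationEpochs = 8, batchSize = 8) {
  list(n = n, ratios = c(0.85, 0.10, 0.05), noiseLevel = 0.15,
       meshDivisor = 25, netConfig = cafnetConfig(),
       epochs = epochs, ablationEpochs = ablationEpochs,
       batchSize = as.integer(batchSize), learningRate = 1e-3, beta1 = 0.5,
       lossWeights = c(0.5, 0.5), trPhantoms = 20L,
       trSettings = trConfig(maxIterations = 12L), seed = as.integer(seed))
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end pipeline
#'
#' generate -> train -> predict on the test split -> evaluate.  Writes the
#' dataset container, the trained model (`model.rds`), a JSON metric report
#' and a manifest with the seeds and the configuration hash.
#'
#' @param config configuration list, see [paperScaledProfile()].
#' @param outDir output directory (created).
#' @param dataset optionally, a pre-generated \linkS4class{DOTDataset} to
#'   reuse instead of generating one.
#' @param verbose progress messages.
#' @return invisible list with the dataset, model, predictions and the
#'   metric report.
#' @export
runPipeline <- function(config = paperScaledProfile(), outDir,
                        dataset = NULL, verbose = FALSE) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  ds <- stageTry("generate", {
    if (is.null(dataset))
      generateDataset(n = config$n, ratios = config$ratios,
                      seed = config$seed, noiseLevel = config$noiseLevel,
                      meshDivisor = config$meshDivisor, verbose = verbose)
    else dataset
  })
  stageTry("generate", writeDataset(ds, file.path(outDir, "dataset")))
  tc <- trainConfig(learningRate = config$learningRate, beta1 = config$beta1,
                    batchSize = config$batchSize, epochs = config$epochs,
                    lossWeights = config$lossWeights,
                    seed = config$seed + 1L)
  model <- stageTry("train", {
    m <- buildCAFNet(config$netConfig, seed = config$seed + 2L)
    trainCAFNet(m, ds, tc, verbose = verbose)
  })
  stageTry("train", saveRDS(model, file.path(outDir, "model.rds")))
  te <- splitIndices(ds, "test")
  pred <- stageTry("predict",
    predictProperties(model, inputMatrix(ds, te), ds@stats))
  report <- stageTry("evaluate", evaluateReconstructions(pred, ds, te))
  agg <- aggregateMetrics(report)
  stageTry("evaluate", jsonlite::write_json(
    list(perSample = report, aggregate = agg),
    file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA))
  manifest <- list(seed = config$seed, configHash = configHash(config),
                   n = nSamples(ds), epochs = config$epochs,
                   package = as.character(utils::packageVersion("fdDOT")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dataset = ds, model = model, predictions = pred,
                 report = report, aggregate = agg))
}

#' Per-sample image metrics of reconstructions against ground truth
#'
#' Computes MSE, PSNR and SSIM per property channel on the normalized scale
#' (dataset training-split statistics) for each reconstructed sample.
#'
#' @param pred N x 64 x 64 x 2 array of reconstructions in physical units.
#' @param ds the \linkS4class{DOTDataset} holding truths and statistics.
#' @param indices dataset sample indices corresponding to the rows of `pred`.
#' @return data.frame with one row per sample and channel.
#' @export
evaluateReconstructions <- function(pred, ds, indices) {
  stopifnot(dim(pred)[1] == length(indices))
  rows <- vector("list", 2L * length(indices))
  for (i in seq_along(indices)) {
    truthN <- normalizeTargets(ds@targets[indices[i], , , ], ds@stats)
    predN <- normalizeTargets(pred[i, , , ], ds@stats)
    for (ch in 1:2) {
      rows[[2 * (i - 1) + ch]] <- data.frame(
        sample = indices[i], channel = c("muA", "muSp")[ch],
        mse = imageMSE(predN[, , ch], truthN[, , ch]),
        psnr = imagePSNR(predN[, , ch], truthN[, , ch]),
        ssim = imageSSIM(predN[, , ch], truthN[, , ch]))
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a per-sample metric table
#' @param report data.frame from [evaluateReconstructions()].
#' @return data.frame of per-channel mean and sd for each metric, with MSE
#'   reported in units of 1e-3 as in the comparison tables.
#' @export
aggregateMetrics <- function(report) {
  agg <- do.call(rbind, lapply(split(report, report$channel), function(d) {
    data.frame(channel = d$channel[1],
               mse1e3Mean = mean(d$mse) * 1e3, mse1e3Sd = stats::sd(d$mse) * 1e3,
               psnrMean = mean(d$psnr[is.finite(d$psnr)]),
               psnrSd = stats::sd(d$psnr[is.finite(d$psnr)]),
               ssimMean = mean(d$ssim), ssimSd = stats::sd(d$ssim))
  }))
  rownames(agg) <- NULL
  agg
}

#' Compare reconstruction methods
#'
#' Aggregates per-sample metric tables of several methods into one
#' comparison table (mean +/- sd of MSE x 1e-3, PSNR, SSIM per channel);
#' methods whose table is NULL are listed as absent.
#'
#' @param reports named list of data.frames from
#'   [evaluateReconstructions()] (or NULL entries).
#' @param csv optional path for a CSV export.
#' @param json optional path for a JSON export.
#' @return data.frame with one row per method and channel.
#' @export
compareMethods <- function(reports, csv = NULL, json = NULL) {
  out <- do.call(rbind, lapply(names(reports), function(nm) {
    if (is.null(reports[[nm]]))
      return(data.frame(method = nm, channel = NA, mse1e3Mean = NA,
                        mse1e3Sd = NA, psnrMean = NA, psnrSd = NA,
                        ssimMean = NA, ssimSd = NA, absent = TRUE))
    cbind(method = nm, aggregateMetrics(reports[[nm]]), absent = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  if (!is.null(json)) jsonlite::write_json(out, json, auto_unbox = TRUE,
                                           digits = NA)
  out
}
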