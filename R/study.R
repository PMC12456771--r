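# Synthetic validation study: generate seeded plants, run the full pipeline,
# and score every recovered trait against the analytic ground truth.

#' Run the pipeline over seeded synthetic plants and score the recovery
#'
#' For each seed a random seedling is drawn (\code{\link{randomPlantSpec}}),
#' the full pipeline is run with the generating stem radius supplied as the
#' "manually measured" diameter, and height, stem length, stem diameter and
#' matched per-leaf areas are compared with the analytic truth; point-level
#' stem F1 and majority-overlap leaf instance recall/precision are computed
#' against the generator labels.
#'
#' @param seeds integer vector of plant seeds
#' @param config_fn function(spec, seed) returning the
#'   \code{\link{pipelineConfig}} to use; the default supplies the known stem
#'   radius and threads the seed
#' @return data.frame with one row per plant: seed, relative errors
#'   (\code{height_err}, \code{stem_length_err}, \code{diameter_err}),
#'   \code{leaf_area_mae} (mean |relative area error| over matched leaves),
#'   \code{stem_f1}, \code{stem_precision}, \code{stem_recall},
#'   \code{leaf_recall}, \code{leaf_precision}, \code{n_true}, \code{n_pred}
#' @export
recoveryStudy <- function(seeds = 1:20,
                          config_fn = function(spec, seed)
                            pipelineConfig(stem_radius = spec$stem_radius,
                                           seed = seed)) {
  rows <- lapply(seeds, function(seed) {
    spec <- randomPlantSpec(seed)
    plant <- generatePlant(spec)
    out <- runPipeline(plant$cloud, config_fn(spec, seed),
                       keep_intermediate = TRUE)
    rep <- out$report
    int <- out$intermediate
    truth <- plant$truth
    sf <- stemF1(int$stem_mask, pointLabels(int$clean))
    li <- leafInstanceScore(pointLabels(int$segmentation),
                            pointLabels(int$leaf_cloud))
    ma <- matchLeafAreas(pointLabels(int$segmentation),
                         pointLabels(int$leaf_cloud),
                         rep@leafAreas, truth$true_leaf_areas)
    data.frame(seed = seed,
               height_err = rep@height / truth$true_height - 1,
               stem_length_err = rep@stemLength / truth$true_stem_length - 1,
               diameter_err = rep@stemDiameter / truth$true_stem_diameter - 1,
               leaf_area_mae = mean(abs(ma$rel_error), na.rm = TRUE),
               stem_f1 = sf[["f1"]],
               stem_precision = sf[["precision"]],
               stem_recall = sf[["recall"]],
               leaf_recall = li[["recall"]],
               leaf_precision = li[["precision"]],
               n_true = li[["n_true"]], n_pred = li[["n_pred"]])
  })
  do.call(rbind, rows)
}
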