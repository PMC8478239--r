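#' Load a workflow configuration
#'
#' Reads a YAML configuration (see the commented template shipped at
#' `system.file("extdata", "config-template.yaml", package = "chaperesp")`)
#' or passes through a list. Relative paths in the file are resolved
#' against its directory.
#'
#' @param config path to a YAML file, or a named list.
#' @return named list.
#' @export
loadConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config)
    cfg <- yaml::read_yaml(config)
    base <- dirname(normalizePath(config))
    for (key in c("structure", "variants", "features", "pssm")) {
      if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
        cfg[[key]] <- file.path(base, cfg[[key]])
    }
    cfg
  } else if (is.list(config)) {
    config
  } else {
    stop("config must be a file path or a list")
  }
}

provenance <- function(config, stage, inputs, params) {
  list(package = "chaperesp",
       version = as.character(utils::packageVersion("chaperesp")),
       stage = stage,
       params = params,
       inputs = lapply(inputs, function(p)
         list(path = p, md5 = unname(tools::md5sum(p)))))
}

writeProvenance <- function(prov, path) {
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Build and write a feature table from a configuration
#'
#' Reads the variant table (and, when configured, the structure, domain
#' ranges, ligand selector and PSSM), assembles the feature table with
#' [buildFeatureTable()] and writes `features.csv` plus a
#' `features-provenance.json` sidecar to the output directory. When no
#' ligand selector is configured the `binds_ligand` column is explicit
#' missing values and a warning is raised.
#'
#' @param config path to a YAML config or a list; recognized fields:
#'   `variants` (required CSV/TSV), `structure` (PDB), `chain`,
#'   `ligand`, `preset` (`"methods"`/`"results"`),
#'   `catalytic_ranges` (list of `[start, end]`), `pssm`, `outdir`.
#' @return path of the written feature CSV, invisibly; the table itself as
#'   the `"table"` attribute.
#' @export
runFeatures <- function(config) {
  cfg <- loadConfig(config)
  if (is.null(cfg$variants)) stop("features stage: config lacks 'variants'")
  outdir <- cfg$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  variants <- tryCatch(readVariants(cfg$variants),
    error = function(e) stop("features stage (variants): ",
                             conditionMessage(e), call. = FALSE))
  structure <- NULL
  if (!is.null(cfg$structure))
    structure <- tryCatch(readPDB(cfg$structure, chain = cfg$chain),
      error = function(e) stop("features stage (structure): ",
                               conditionMessage(e), call. = FALSE))
  cmap <- NULL
  if (!is.null(structure)) {
    preset <- cfg$preset %||% "methods"
    cmap <- computeContacts(structure, contactParams(preset))
  }
  domains <- NULL
  if (!is.null(cfg$catalytic_ranges))
    domains <- do.call(rbind, lapply(cfg$catalytic_ranges, function(r)
      data.frame(start = r[[1]], end = r[[2]])))
  pssm <- if (!is.null(cfg$pssm)) readPSSM(cfg$pssm) else NULL
  if (is.null(cfg$ligand) && !"binds_ligand" %in% names(variants))
    warning("no ligand selector configured; binds_ligand will be NA")

  tab <- buildFeatureTable(variants, structure = structure, cmap = cmap,
                           ligand_selector = cfg$ligand,
                           domain_config = domains, pssm = pssm)
  out_csv <- file.path(outdir, "features.csv")
  utils::write.csv(tab, out_csv, row.names = FALSE)
  writeProvenance(
    provenance(cfg, "features",
               inputs = Filter(Negate(is.null),
                               cfg[c("variants", "structure", "pssm")]),
               params = list(preset = cfg$preset %||% "methods",
                             chain = cfg$chain, ligand = cfg$ligand)),
    file.path(outdir, "features-provenance.json"))
  attr(out_csv, "table") <- tab
  invisible(out_csv)
}

#' Predict responsiveness from a feature table file
#'
#' Applies the rule cascade ([predictTreeBatch()]) to a feature CSV and
#' writes `predictions.csv` (`variant`, `responsive`, `p1`, `leaf`,
#' `trace`) plus a provenance sidecar.
#'
#' @param config path or list; fields `features` (CSV path, required),
#'   `thresholds` (named list of [treeThresholds()] overrides),
#'   `leaf_probs` (named list of [defaultLeafProbs()] overrides),
#'   `outdir`.
#' @return path of the predictions CSV, invisibly; table as `"table"`
#'   attribute.
#' @export
runPredict <- function(config) {
  cfg <- loadConfig(config)
  if (is.null(cfg$features)) stop("predict stage: config lacks 'features'")
  outdir <- cfg$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  feats <- utils::read.csv(cfg$features, stringsAsFactors = FALSE)
  need <- c("ddg", "binds_ligand", "n_contacts", "p_inv")
  miss <- setdiff(need, names(feats))
  if (length(miss) > 0)
    stop("predict stage: feature table lacks column(s): ",
         paste(miss, collapse = ", "))
  th <- do.call(treeThresholds, cfg$thresholds %||% list())
  lp <- do.call(defaultLeafProbs, cfg$leaf_probs %||% list())
  preds <- predictTreeBatch(feats, thresholds = th, leaves = lp)
  out_csv <- file.path(outdir, "predictions.csv")
  utils::write.csv(preds, out_csv, row.names = FALSE)
  writeProvenance(
    provenance(cfg, "predict", inputs = cfg["features"],
               params = list(thresholds = cfg$thresholds,
                             leaf_probs = cfg$leaf_probs)),
    file.path(outdir, "predictions-provenance.json"))
  attr(out_csv, "table") <- preds
  invisible(out_csv)
}

#' Run the kinetic sweep from a configuration
#'
#' Computes the four rescue curves (unfolding/folding mode, chaperone
#' on/off) over a stability-change grid and writes them as one tidy CSV
#' plus a provenance sidecar.
#'
#' @param config path or list; fields `ddg_min` (default 0), `ddg_max`
#'   (default 4), `step` (default 0.05), `outdir`.
#' @return path of the sweep CSV, invisibly; table as `"table"` attribute.
#' @export
runKinetics <- function(config = list()) {
  cfg <- loadConfig(config)
  outdir <- cfg$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- seq(cfg$ddg_min %||% 0, cfg$ddg_max %||% 4,
              by = cfg$step %||% 0.05)
  tab <- do.call(rbind, lapply(c("unfolding", "folding"), function(m)
    do.call(rbind, lapply(c(TRUE, FALSE), function(ch)
      rescueCurve(grid, mode = m, chaperone = ch)))))
  out_csv <- file.path(outdir, "kinetics.csv")
  utils::write.csv(tab, out_csv, row.names = FALSE)
  writeProvenance(
    provenance(cfg, "kinetics", inputs = list(),
               params = list(ddg_min = cfg$ddg_min %||% 0,
                             ddg_max = cfg$ddg_max %||% 4,
                             step = cfg$step %||% 0.05)),
    file.path(outdir, "kinetics-provenance.json"))
  attr(out_csv, "table") <- tab
  invisible(out_csv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
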