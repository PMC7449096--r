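#' Default pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Every parameter of
#' every stage is a top-level key so that a whole batch campaign can be
#' reproduced from one small text file; explicit arguments override file
#' values.
#'
#' @return Named list of defaults.
#' @export
pipeline_config <- function() {
  list(
    input = NULL,                 # path to the volume (or pass a volume object)
    voxel_size_mm = NULL,         # required for TIFF input
    accession_id = "NA",
    tau = NULL,                   # NULL = automatic histogram estimate
    gaussian_sigma_mm = 0.1,
    morph_radius_vox = 1L,
    min_spot_mm3 = 100,
    connectivity = 26L,
    split_touching = FALSE,
    min_seed_distance_mm = 10,
    margin_mm = 1.0,
    k_clusters = 3L,              # per-crop clustering; crops carry no foam
    feret_directions = 2000L,
    swap_face_profile = FALSE,
    out_dir = NULL                # if set: traits.csv + qc_report.json
  )
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and `#`
#' comments ignored. Values are parsed as logical/numeric where possible.
#'
#' @param path configuration file.
#' @return Named list merged over [pipeline_config()] defaults.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- pipeline_config()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=:]+)[=:]\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("cannot parse config line: ", ln)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- parse_config_value(val)
  }
  cfg
}

parse_config_value <- function(val) {
  if (tolower(val) %in% c("true", "false")) return(tolower(val) == "true")
  if (tolower(val) %in% c("null", "auto", "")) return(NULL)
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

#' Run the full phenotyping pipeline on one scan
#'
#' Orchestrates the complete workflow on a batch volume: preprocessing
#' (smooth, threshold, clean), individualization (label, optional touching
#' split, crop), per-nut part segmentation, shell-integrity QC and trait
#' quantification. Returns the trait table of all QC-passed nuts plus a QC
#' report that lists excluded nuts with reasons and echoes every parameter
#' used, so a run is fully reproducible from its report. The pipeline is
#' deterministic: identical input and configuration give identical output.
#'
#' @param x a [volume3d()], or a path readable by [read_volume()], or a
#'   config list/path whose `input` key names the volume.
#' @param config a config list (see [pipeline_config()]) or path to a flat
#'   key = value file; `...` overrides individual keys.
#' @param ... individual config overrides.
#' @return List with `traits` (data.frame; QC-passed nuts only), `qc_report`
#'   (list: parameters, per-stage voxel counts, per-nut status, exclusions).
#' @export
run_pipeline <- function(x, config = pipeline_config(), ...) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- utils::modifyList(pipeline_config(), config)
  config <- utils::modifyList(config, list(...))

  if (inherits(x, "nut_volume")) {
    vol <- x
  } else if (is.character(x)) {
    vol <- with_stage("read", "-", read_volume(x, config$voxel_size_mm))
  } else stop("x must be a nut_volume or a file path")

  pre <- with_stage("preprocess", "-", preprocess_volume(
    vol, preprocess_params(tau = config$tau,
                           gaussian_sigma_mm = config$gaussian_sigma_mm,
                           morph_radius_vox = config$morph_radius_vox,
                           min_spot_mm3 = config$min_spot_mm3)))
  labs <- with_stage("individualize", "-",
                     label_walnuts(pre$mask, config$connectivity))
  if (isTRUE(config$split_touching))
    labs <- with_stage("split", "-",
                       split_touching(labs, config$min_seed_distance_mm))
  crops <- with_stage("crop", "-",
                      crop_subvolumes(vol, labs, config$margin_mm))

  rows <- list(); nuts <- list(); excluded <- list()
  for (cr in crops) {
    id <- as.character(cr$label)
    cl <- with_stage("cluster", id,
                     cluster_histogram(cr$volume, config$k_clusters))
    pm <- with_stage("segment", id, segment_nut_parts(cr$volume, cl))
    row <- with_stage("measure", id, measure_walnut(
      pm, accession_id = config$accession_id, nut_id = id,
      feret_directions = config$feret_directions,
      swap_face_profile = config$swap_face_profile))
    status <- list(nut_id = id, qc = row$qc, qc_reason = row$qc_reason,
                   n_voxels = cr$n_voxels)
    nuts[[id]] <- status
    if (row$qc == "pass") rows[[id]] <- row else excluded[[id]] <- status
  }
  traits <- if (length(rows)) do.call(rbind, unname(rows)) else
    cbind(data.frame(accession_id = character(), nut_id = character()),
          as.data.frame(stats::setNames(
            rep(list(numeric()), length(trait_columns())),
            names(trait_columns()))),
          data.frame(qc = character(), qc_reason = character()))
  report <- list(
    parameters = config[setdiff(names(config), "out_dir")],
    tau = pre$tau,
    voxel_counts = list(foreground = sum(pre$mask$data),
                        labelled = sum(labs$data > 0)),
    n_nuts = labs$n_labels,
    nuts = unname(nuts),
    excluded = unname(excluded)
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trait_table(traits, file.path(config$out_dir, "traits.csv"))
    jsonlite::write_json(report, file.path(config$out_dir, "qc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  list(traits = traits, qc_report = report)
}

# stage wrapper: any failure is rethrown with the stage name and nut id
with_stage <- function(stage, nut_id, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed",
         if (!identical(nut_id, "-")) paste0(" for nut ", nut_id) else "",
         ": ", conditionMessage(e), call. = FALSE)
  })
}
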