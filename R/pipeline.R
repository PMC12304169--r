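#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end workflow together with
#' stage toggles and the global seed. With no external inputs the pipeline
#' runs on a synthetic survey generated from `survey`.
#'
#' @param out_dir Output directory for stage artefacts and the manifest.
#' @param survey A [survey_config()] used when no external navigation /
#'   detections are supplied.
#' @param navigation,detections Optional external input tibbles (or paths
#'   to CSV files with the standard schemas).
#' @param enhance,cluster,standardise,hotspots,community Stage toggles.
#' @param batch_size,k_range,unit_length_m,k_neighbours,n_bins,n_perm,alpha
#'   Stage parameters (defaults: 32-image batches, k scanned over 2..20,
#'   100 m sampling units, 6 nearest neighbours, 8 quantile bins, 999
#'   permutations, 0.05 significance).
#' @param camera A [camera_geometry()] (48 x 33 degrees by default).
#' @param reference_image_id Histogram-matching reference; defaults to the
#'   middle image of the collection as a deterministic stand-in for the
#'   operator's manual choice.
#' @param max_images Cap on the number of images run through the image
#'   stages (`NULL` = all).
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("benthoscan_run_"),
                            survey = survey_config(),
                            navigation = NULL, detections = NULL,
                            enhance = TRUE, cluster = TRUE,
                            standardise = TRUE, hotspots = TRUE,
                            community = TRUE,
                            batch_size = 32, k_range = 2:20,
                            unit_length_m = 100, k_neighbours = 6,
                            n_bins = 8, n_perm = 999, alpha = 0.05,
                            camera = camera_geometry(),
                            reference_image_id = NULL,
                            max_images = NULL,
                            seed = 1L) {
  stopifnot(batch_size >= 2, unit_length_m > 0, k_neighbours >= 1,
            n_bins >= 2, n_perm >= 99, alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate survey inputs
#'
#' Schema and consistency checks for navigation and detection tables:
#' required columns, strictly increasing timestamps within a dive,
#' positive altitudes, detections referencing known images and
#' non-negative box geometry. Never raises; returns a machine-readable
#' issue list, empty when the inputs are clean.
#'
#' @param navigation Navigation tibble.
#' @param detections Detection tibble.
#' @return Tibble of issues: `table`, `record`, `issue`.
#' @export
validate_inputs <- function(navigation, detections) {
  issues <- list()
  add <- function(table, record, issue) {
    issues[[length(issues) + 1]] <<- tibble(table = table, record = record,
                                            issue = issue)
  }
  need_nav <- c("image_id", "dive_id", "timestamp_s", "lon_deg", "lat_deg",
                "altitude_m")
  miss <- setdiff(need_nav, names(navigation))
  if (length(miss) > 0) {
    add("navigation", NA_character_,
        paste0("missing column(s): ", paste(miss, collapse = ", ")))
    return(dplyr::bind_rows(issues))
  }
  bad_alt <- navigation$image_id[navigation$altitude_m <= 0]
  for (id in bad_alt) add("navigation", id, "non-positive altitude")
  for (dv in unique(navigation$dive_id)) {
    ts <- navigation$timestamp_s[navigation$dive_id == dv]
    if (any(diff(sort(ts)) == 0) || is.unsorted(ts)) {
      if (anyDuplicated(ts)) {
        add("navigation", as.character(dv), "duplicate timestamps in dive")
      } else if (is.unsorted(ts)) {
        add("navigation", as.character(dv), "timestamps not sorted in dive")
      }
    }
  }
  dup <- navigation$image_id[duplicated(navigation$image_id)]
  for (id in unique(dup)) add("navigation", id, "duplicate image_id")
  need_det <- c("image_id", "taxon")
  miss <- setdiff(need_det, names(detections))
  if (length(miss) > 0) {
    add("detections", NA_character_,
        paste0("missing column(s): ", paste(miss, collapse = ", ")))
    return(dplyr::bind_rows(issues))
  }
  unknown <- unique(setdiff(detections$image_id, navigation$image_id))
  for (id in unknown) add("detections", id, "unknown image_id")
  if (all(c("w", "h") %in% names(detections))) {
    bad <- which(detections$w <= 0 | detections$h <= 0)
    for (i in bad) add("detections", detections$image_id[i],
                       "non-positive box size")
  }
  if (length(issues) == 0) {
    return(tibble(table = character(), record = character(),
                  issue = character()))
  }
  dplyr::bind_rows(issues)
}

read_table_arg <- function(x) {
  if (is.character(x)) readr::read_csv(x, show_col_types = FALSE) else x
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — image enhancement, habitat
#' clustering, abundance standardisation, hotspot analysis, community
#' statistics — writing every artefact as CSV into `config$out_dir`
#' together with a manifest (parameters, seed, package version). Rerunning
#' with the same configuration and seed reproduces identical outputs.
#' Image stages process the collection in batches so the whole collection
#' is never held in memory.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list of in-memory stage results (`navigation`,
#'   `detections`, `units`, `abundance`, `overlap`, `decorrelation`,
#'   `lisa`, `bins`, `habitat`, `community`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, t) {
    timings[[stage]] <<- round(as.numeric(Sys.time()) - as.numeric(t), 2)
  }

  # --- inputs ---------------------------------------------------------------
  t <- Sys.time()
  external <- !is.null(config$navigation)
  if (external) {
    nav <- read_table_arg(config$navigation)
    det <- read_table_arg(config$detections)
  } else {
    nav <- generate_navigation(config$survey, config$seed)
    det <- generate_detections(nav, config$survey, config$seed)
  }
  issues <- validate_inputs(nav, det)
  if (nrow(issues) > 0) {
    readr::write_csv(issues, file.path(config$out_dir, "issues.csv"))
    abort(paste0("stage 'inputs' failed: ", nrow(issues),
                 " validation issue(s); first: ", issues$issue[1],
                 " (", issues$table[1], " ", issues$record[1], ")"))
  }
  readr::write_csv(nav, file.path(config$out_dir, "navigation.csv"))
  readr::write_csv(det, file.path(config$out_dir, "detections.csv"))
  tick("inputs", t)

  results <- list(navigation = nav, detections = det)

  # --- image stages: enhancement + habitat clustering -----------------------
  if ((config$enhance || config$cluster) && !external) {
    t <- Sys.time()
    nav_img <- nav
    if (!is.null(config$max_images)) {
      nav_img <- dplyr::slice_head(nav, n = config$max_images)
    }
    ids <- nav_img$image_id
    ref_id <- config$reference_image_id %||% ids[ceiling(length(ids) / 2)]
    ec <- enhancement_config(batch_size = config$batch_size,
                             reference_image_id = ref_id)
    batches <- batch_indices(length(ids), config$batch_size)
    # images are produced, enhanced and encoded one batch at a time; only
    # the features survive, so the whole collection never sits in memory
    run_batch <- function(b) {
      imgs <- generate_images(nav_img[b, ], config$survey, config$seed)
      step2 <- if (config$enhance) {
        zs <- batch_zscore(setNames(imgs$image, imgs$image_id), ec$epsilon)
        lapply(zs, adaptive_hist_eq, config = ec)
      } else {
        setNames(imgs$image, imgs$image_id)
      }
      list(step2 = step2, substrate = setNames(imgs$substrate,
                                               imgs$image_id))
    }
    ref <- NULL
    if (config$enhance) {
      ref_batch <- batches[[which(vapply(batches, function(b)
        ref_id %in% ids[b], logical(1)))[1]]]
      ref <- run_batch(ref_batch)$step2[[ref_id]]
    }
    if (config$cluster) {
      feats <- NULL
      truth <- character(0)
      for (b in batches) {
        rb <- run_batch(b)
        truth <- c(truth, rb$substrate)
        enhanced <- if (config$enhance) {
          lapply(rb$step2, histogram_match, reference = ref)
        } else {
          rb$step2
        }
        feats <- rbind(feats, extract_feature_matrix(enhanced))
      }
      k <- select_k(feats, config$k_range, seed = config$seed)
      model <- cluster_habitats(feats, k, seed = config$seed)
      labels <- dplyr::left_join(
        model$labels,
        tibble(image_id = names(truth), substrate_truth = unname(truth)),
        by = "image_id"
      )
      readr::write_csv(labels, file.path(config$out_dir,
                                         "cluster_labels.csv"))
      readr::write_csv(attr(k, "curve"),
                       file.path(config$out_dir, "selection_curve.csv"))
      proj <- project_pca(feats)
      readr::write_csv(proj, file.path(config$out_dir, "pca.csv"))
      results$habitat <- list(k = k, model = model, labels = labels,
                              projection = proj)
    }
    tick("images", t)
  }

  # --- standardisation ------------------------------------------------------
  if (config$standardise) {
    t <- Sys.time()
    nav <- along_track_positions(nav)
    units <- partition_units(nav, config$unit_length_m)
    abund <- pool_and_standardise(units, nav, det, config$camera)
    abund <- unit_covariates(abund, if (external) NULL else config$survey,
                             seed = config$seed)
    overlap <- check_overlap(nav, config$camera)
    deco <- decorrelation_check(abund)
    readr::write_csv(as_tibble(as.data.frame(abund)),
                     file.path(config$out_dir, "abundance.csv"))
    readr::write_csv(overlap, file.path(config$out_dir, "overlap.csv"))
    readr::write_csv(deco, file.path(config$out_dir, "decorrelation.csv"))
    results$units <- units
    results$abundance <- abund
    results$overlap <- overlap
    results$decorrelation <- deco
    tick("standardise", t)
  }

  # --- hotspot analysis -----------------------------------------------------
  if (config$hotspots) {
    if (is.null(results$abundance)) {
      abort("stage 'hotspots' failed: requires the standardisation stage")
    }
    t <- Sys.time()
    abund <- results$abundance
    total <- rowSums(abundance_values(abund))
    w <- knn_graph(abund, k = config$k_neighbours)
    lisa <- local_moran(total, w, n_perm = config$n_perm,
                        seed = config$seed, alpha = config$alpha)
    bins <- quantile_bins(total, config$n_bins)
    bins_tbl <- tibble(unit_id = abund$unit_id, abundance = total,
                       bin = as.integer(bins))
    readr::write_csv(tidy(lisa), file.path(config$out_dir, "lisa.csv"))
    readr::write_csv(bins_tbl, file.path(config$out_dir, "bins.csv"))
    results$lisa <- lisa
    results$bins <- bins_tbl
    results$global_moran <- morans_i(total, w)
    tick("hotspots", t)
  }

  # --- community statistics -------------------------------------------------
  if (config$community) {
    if (is.null(results$abundance)) {
      abort("stage 'community' failed: requires the standardisation stage")
    }
    t <- Sys.time()
    abund <- results$abundance
    mat <- abundance_values(abund)
    nonzero <- rowSums(mat) > 0
    tr <- double_root(mat[nonzero, , drop = FALSE])
    d <- suppressWarnings(bray_curtis(tr))
    groups <- abund$region[nonzero]
    an <- anosim_test(d, groups, n_perm = config$n_perm, seed = config$seed)
    sim <- simper_table(tr, groups)
    tree <- upgma_cluster(d, k = 2)
    ord <- nmds_ordination(d, dims = 2, n_starts = 20, seed = config$seed)
    env_vars <- intersect(c("depth_m", "slope", "tpi", "tri", "salinity",
                            "temperature", "longitude"), names(abund))
    env <- as.data.frame(abund)[nonzero, env_vars, drop = FALSE]
    fits <- suppressWarnings(
      fit_vectors(ord, env, n_perm = config$n_perm, seed = config$seed)
    )
    shan <- tibble(region = abund$region[nonzero],
                   h = shannon_index(mat[nonzero, , drop = FALSE]),
                   total = rowSums(mat[nonzero, , drop = FALSE])) |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(mean_shannon = mean(.data$h),
                       mean_abundance = mean(.data$total),
                       sd_abundance = sd(.data$total),
                       .groups = "drop")
    readr::write_csv(glance(an), file.path(config$out_dir, "anosim.csv"))
    readr::write_csv(as_tibble(sim), file.path(config$out_dir, "simper.csv"))
    readr::write_csv(tidy(ord), file.path(config$out_dir, "nmds.csv"))
    readr::write_csv(fits, file.path(config$out_dir, "envfit.csv"))
    readr::write_csv(shan, file.path(config$out_dir, "shannon.csv"))
    results$community <- list(anosim = an, simper = sim, upgma = tree,
                              nmds = ord, envfit = fits, shannon = shan)
    tick("community", t)
  }

  manifest <- list(
    package = "benthoscan",
    version = as.character(utils::packageVersion("benthoscan")),
    seed = config$seed,
    external_inputs = external,
    parameters = list(batch_size = config$batch_size,
                      k_range = range(config$k_range),
                      unit_length_m = config$unit_length_m,
                      k_neighbours = config$k_neighbours,
                      n_bins = config$n_bins, n_perm = config$n_perm,
                      alpha = config$alpha,
                      camera = unclass(config$camera)[1:2]),
    stages = timings,
    n_images = nrow(nav), n_detections = nrow(det),
    total_s = round(as.numeric(Sys.time()) - as.numeric(t0), 2)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Write a synthetic survey to disk
#'
#' Navigation, detections and ground-truth intensity tables as CSV;
#' optionally the images as PNG (requires the \pkg{png} package).
#'
#' @param survey A [simulate_survey()] result.
#' @param dir Output directory.
#' @param images Also write PNG images (only if present in `survey`)?
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir, images = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(survey$navigation, file.path(dir, "navigation.csv"))
  readr::write_csv(survey$detections, file.path(dir, "detections.csv"))
  readr::write_csv(survey$ground_truth$intensity,
                   file.path(dir, "truth_intensity.csv"))
  readr::write_csv(survey$ground_truth$hotspots,
                   file.path(dir, "truth_hotspots.csv"))
  if (images && !is.null(survey$images)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("writing PNG images requires the 'png' package")
    }
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    purrr::walk2(survey$images$image, survey$images$image_id, function(im, id) {
      png::writePNG(im, file.path(img_dir, paste0(id, ".png")))
    })
  }
  invisible(dir)
}
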