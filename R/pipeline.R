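# Run configuration, pipeline driver and file exports.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its default: standard length
#' (`L = NULL` -> cohort median), angular resolution 5 degrees, 100,000
#' permutations, supra-significance alpha 1e-3, one-sided "decrease"
#' direction, mean-difference statistic, 0.3 mm working voxel and equal-
#' sixths vertebral boundaries.
#'
#' @param out_dir output directory.
#' @param mode `"simulate"` (generate a phantom cohort) or `"volumes"`
#'   (read NIfTI volumes + landmark sidecars from `volumes_dir`).
#' @param cohort a [cohort_spec] (simulate mode).
#' @param phantom a [phantom_spec] (simulate mode).
#' @param volumes_dir,landmarks_dir,masks_dir input directories for volume
#'   mode; when `masks_dir` is set segmentation is skipped and external
#'   masks are ingested instead.
#' @param skip_segmentation use masks from `masks_dir`.
#' @param L standard slice count (`NULL` = cohort lower-median length).
#' @param angular_res angular resolution in degrees (must divide 360).
#' @param n_perm,alpha,side,statistic permutation-map settings.
#' @param boundaries vertebral boundary fractions, see [label_levels()].
#' @param target_voxel_mm,margin_mm,bias_poly_order preprocessing settings
#'   (`bias_poly_order = 0` disables bias correction).
#' @param t_low_q,t_high_q segmentation quantiles.
#' @param rd also compute radial-distance maps (slower).
#' @param seed master RNG seed.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = "cordmorph_out",
                       mode = c("simulate", "volumes"),
                       cohort = cohort_spec(), phantom = phantom_spec(),
                       volumes_dir = NULL, landmarks_dir = NULL,
                       masks_dir = NULL, skip_segmentation = !is.null(masks_dir),
                       L = NULL, angular_res = 5, n_perm = 100000L,
                       alpha = 1e-3, side = "decrease", statistic = "mean_diff",
                       boundaries = (1:5) / 6,
                       target_voxel_mm = 0.3, margin_mm = 20,
                       bias_poly_order = 0L, t_low_q = 0.5, t_high_q = 0.8,
                       rd = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  if (360 %% angular_res != 0) stop("angular_res must divide 360")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  cfg <- list(out_dir = out_dir, mode = mode, cohort = cohort,
              phantom = phantom, volumes_dir = volumes_dir,
              landmarks_dir = landmarks_dir, masks_dir = masks_dir,
              skip_segmentation = skip_segmentation, L = L,
              angular_res = angular_res, n_perm = as.integer(n_perm),
              alpha = alpha, side = side, statistic = statistic,
              boundaries = boundaries, target_voxel_mm = target_voxel_mm,
              margin_mm = margin_mm, bias_poly_order = as.integer(bias_poly_order),
              t_low_q = t_low_q, t_high_q = t_high_q, rd = rd,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialization; embedded in every output file so
#' that results can be traced to the exact configuration.
#'
#' @param config a [run_config()].
#' @return Character hash.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL   # hash the analysis configuration, not its destination
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 10,
                         force = TRUE, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

write_csv_hashed <- function(x, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", hash), con)
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

read_csv_hashed <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Export a p-value map as a 2D heat map PNG
#'
#' Slices (inferior to superior) on the horizontal axis, angles on the
#' vertical axis; color encodes -log10(p), masked below `alpha`.
#'
#' @param map a [permutation_map()] result with a matrix `p`.
#' @param path PNG output path.
#' @param alpha significance threshold used for the overlay.
#' @return `path`, invisibly.
#' @export
export_pvalue_heatmap <- function(map, path, alpha = map$alpha) {
  p <- map$p
  if (is.null(dim(p))) p <- matrix(p, ncol = 1L)
  png(path, width = 900, height = 400)
  on.exit(dev.off())
  lp <- -log10(p)
  image(x = seq_len(nrow(p)), y = seq_len(ncol(p)), z = lp,
        col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "standardized slice (inferior -> superior)",
        ylab = if (ncol(p) > 1L) "angle bin (0 deg = anterior)" else "",
        main = sprintf("-log10(p), %d sites < %g", sum(p < alpha), alpha))
  box()
  invisible(path)
}

stage <- function(name, id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for subject '%s': %s",
                 name, id, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> segment (or external-mask ingestion) ->
#' straighten -> standardize -> morphometry -> statistics, and writes all
#' outputs (profiles, permutation maps, atrophy rate, clinical correlations,
#' summary table) plus a provenance log to `config$out_dir`. Every CSV/JSON
#' output embeds the configuration hash; reruns with an identical
#' configuration are bit-identical.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`profiles`,
#'   `csa_map`, `rd_map`, `atrophy_rate`, `correlations`, `table1`,
#'   `config_hash`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$mode == "simulate") {
    man <- cohort_manifest(config$cohort, config$phantom)
    records <- man$records
    ids <- records$id
    get_input <- function(i) {
      ph <- stage("simulate", ids[i], subject_phantom(man, i, render_volume = TRUE))
      list(volume = ph$volume,
           landmarks = landmark_pair(
             superior = c(0L, 0L, n_slices(ph$volume) - 1L),
             inferior = c(0L, 0L, 0L)),
           mask_path = NULL)
    }
    n <- length(ids)
  } else {
    vol_files <- sort(list.files(config$volumes_dir, pattern = "\\.nii(\\.gz)?$",
                                 full.names = TRUE))
    if (length(vol_files) == 0L) stop("no NIfTI volumes in ", config$volumes_dir)
    ids <- sub("\\.nii(\\.gz)?$", "", basename(vol_files))
    records <- NULL
    rec_file <- file.path(config$volumes_dir, "records.csv")
    if (file.exists(rec_file)) records <- read_csv_hashed(rec_file)
    get_input <- function(i) {
      vol <- stage("read", ids[i], read_nifti(vol_files[i]))
      lmf <- file.path(if (is.null(config$landmarks_dir)) config$volumes_dir
                       else config$landmarks_dir, paste0(ids[i], ".json"))
      lm <- if (file.exists(lmf)) read_landmarks(lmf)
            else landmark_pair(c(0L, 0L, n_slices(vol) - 1L), c(0L, 0L, 0L))
      mp <- if (!is.null(config$masks_dir)) {
        cand <- list.files(config$masks_dir, full.names = TRUE,
                           pattern = paste0("^", ids[i], ".*\\.nii(\\.gz)?$"))
        if (length(cand) == 0L) stop("no mask for subject ", ids[i])
        cand[1L]
      } else NULL
      list(volume = vol, landmarks = lm, mask_path = mp)
    }
    n <- length(ids)
  }

  straightened <- vector("list", n)
  lengths_n <- integer(n)
  for (i in seq_len(n)) {
    inp <- get_input(i)
    vol <- inp$volume
    if (config$bias_poly_order > 0L)
      vol <- stage("bias-correction", ids[i],
                   correct_bias(vol, config$bias_poly_order))
    vol <- stage("crop-resample", ids[i],
                 crop_and_resample(vol, inp$landmarks,
                                   target_voxel_mm = config$target_voxel_mm,
                                   margin_mm = config$margin_mm))
    mask <- if (config$skip_segmentation && !is.null(inp$mask_path)) {
      stage("mask-ingestion", ids[i], load_external_mask(inp$mask_path, vol))
    } else {
      stage("segmentation", ids[i],
            segment_dtbm(vol, t_low_q = config$t_low_q,
                         t_high_q = config$t_high_q))
    }
    st <- stage("straightening", ids[i], straighten(mask))
    straightened[[i]] <- st$mask
    lengths_n[i] <- n_slices(st$mask)
    rm(inp, vol, mask, st)
  }
  L <- if (is.null(config$L)) cohort_standard_length(lengths_n)
       else as.integer(config$L)
  n_ang <- as.integer(360 / config$angular_res)
  csa <- matrix(NA_real_, n, L, dimnames = list(ids, NULL))
  rdm <- if (config$rd) matrix(NA_real_, n, L * n_ang,
                               dimnames = list(ids, NULL)) else NULL
  for (i in seq_len(n)) {
    sm <- stage("standardization", ids[i],
                standardize_length(straightened[[i]], L))
    csa[i, ] <- stage("morphometry", ids[i], cross_sectional_areas(sm))
    if (config$rd)
      rdm[i, ] <- as.vector(stage("morphometry", ids[i],
                                  radial_distances(sm, config$angular_res)))
    straightened[i] <- list(NULL)
  }
  level_map <- label_levels(L, config$boundaries)

  # ---- statistics --------------------------------------------------------
  res <- list(config_hash = hash, L = L, level_map = level_map,
              profiles = list(csa = csa, rd = rdm), records = records)
  is_pat <- if (!is.null(records)) records$group == "patient"
            else rep(FALSE, n)
  if (sum(is_pat) >= 2L && sum(!is_pat) >= 2L) {
    res$csa_map <- permutation_map(csa[is_pat, , drop = FALSE],
                                   csa[!is_pat, , drop = FALSE],
                                   n_perm = config$n_perm, alpha = config$alpha,
                                   side = config$side,
                                   statistic = config$statistic,
                                   seed = config$seed)
    res$atrophy_rate <- atrophy_rate(csa[is_pat, , drop = FALSE],
                                     csa[!is_pat, , drop = FALSE],
                                     map = res$csa_map)
    if (config$rd) {
      res$rd_map <- permutation_map(
        array(rdm[is_pat, ], c(sum(is_pat), L, n_ang)),
        array(rdm[!is_pat, ], c(sum(!is_pat), L, n_ang)),
        n_perm = config$n_perm, alpha = config$alpha, side = config$side,
        statistic = config$statistic, seed = config$seed)
    }
    score_fields <- intersect(c("disease_duration_years", "mmt_pct_c5",
                                "mmt_pct_c6", "mmt_pct_c7", "mmt_pct_c8",
                                "mfm_d1", "mfm_d2", "mfm_d3",
                                "alsfrs_arm", "alsfrs_leg", "alsfrs_total"),
                              names(records))
    res$correlations <- list()
    for (f in score_fields) {
      sc <- records[[f]][is_pat]
      if (sum(is.finite(sc)) >= 4L && sd(sc, na.rm = TRUE) > 0)
        res$correlations[[f]] <- correlate_profiles(
          csa[is_pat, , drop = FALSE], sc, alpha = config$alpha)
    }
    if (all(c("mmt_pct_c5", "mmt_pct_c8") %in% names(records)) &&
        sum(is_pat) >= 4L) {
      res$proximal_distal <- proximal_distal_test(
        records$mmt_pct_c5[is_pat], records$mmt_pct_c8[is_pat])
      mm <- as.matrix(records[is_pat, c("mmt_pct_c5", "mmt_pct_c6",
                                        "mmt_pct_c7", "mmt_pct_c8")])
      res$gradient <- gradient_correlation(csa[is_pat, , drop = FALSE],
                                           level_map, mm,
                                           voxel_mm = config$target_voxel_mm)
    }
    if (!is.null(records)) res$table1 <- table1_summary(records)
  }

  # ---- outputs -----------------------------------------------------------
  od <- config$out_dir
  write_csv_hashed(as.data.frame(csa), file.path(od, "csa_profiles.csv"), hash)
  if (!is.null(res$csa_map)) {
    write_csv_hashed(data.frame(slice = seq_len(L) - 1L,
                                statistic = res$csa_map$statistic,
                                p = res$csa_map$p,
                                significant = res$csa_map$significant,
                                atrophy_rate_pct = as.numeric(res$atrophy_rate)),
                     file.path(od, "csa_map.csv"), hash)
  }
  if (!is.null(res$rd_map)) {
    pm <- as.data.frame(res$rd_map$p)
    names(pm) <- sprintf("deg%03d", as.integer((seq_len(n_ang) - 1) * config$angular_res))
    write_csv_hashed(cbind(slice = seq_len(L) - 1L, pm),
                     file.path(od, "rd_pmap.csv"), hash)
  }
  if (!is.null(res$table1))
    write_csv_hashed(res$table1, file.path(od, "table1.csv"), hash)
  for (f in names(res$correlations)) {
    cm <- res$correlations[[f]]
    write_csv_hashed(data.frame(slice = seq_len(L) - 1L, rho = cm$rho,
                                p = cm$p, significant = cm$significant),
                     file.path(od, paste0("correlation_", f, ".csv")), hash)
  }
  if (!is.null(records))
    write_csv_hashed(records, file.path(od, "records.csv"), hash)
  prov <- list(config_hash = hash,
               package_version = as.character(utils::packageVersion("cordmorph")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               L = L, n_subjects = n,
               config = unclass(config)[setdiff(names(config),
                                                c("cohort", "phantom", "out_dir"))])
  jsonlite::write_json(prov, file.path(od, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       null = "null", digits = 10)
  invisible(res)
}
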