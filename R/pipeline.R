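#' Pipeline run configuration
#'
#' Bundles the stage configurations and the combination matrix (which
#' populations act as targets, which supply reference panels, and which
#' arrays are mimicked) for \code{\link{run_pipeline}}.  A single seed
#' drives every stage; derived stage seeds are deterministic offsets of
#' it, so a fixed \code{seed} reproduces the whole run bit-for-bit.
#'
#' @param sim a \code{\link{sim_config}} (its own seed is overridden by
#'   \code{seed}).
#' @param qc a \code{\link{qc_thresholds}} applied to each reference
#'   half before it becomes a reference panel.
#' @param ls an \code{\link{ls_params}}.
#' @param meta a \code{\link{meta_params}}.
#' @param bins an \code{\link{af_bins}}.
#' @param varld a \code{\link{varld_config}} for the inter-population
#'   LD scan (first two populations).
#' @param n_target held-out target samples per population.
#' @param array_density,array_maf_floor,ld_r2_tag array-design knobs
#'   passed to \code{\link{design_array}}.
#' @param impute_maf_floor pre-phasing MAF floor on the typed panel.
#' @param target_pops populations evaluated as imputation targets
#'   (default: first population).
#' @param array_pops populations an array is designed for (default:
#'   all).
#' @param ref_pops populations supplying reference panels (default:
#'   all).
#' @param do_meta combine all reference panels by meta-imputation.
#' @param do_varld run the varLD stage (needs >= 2 populations).
#' @param switch_error_rate per-het phase switch-error rate injected
#'   into target phase.
#' @param seed master seed.
#' @param out_dir optional directory; when set, every artifact is
#'   written with a provenance header (seed + config hash).
#' @return List of class \code{run_config}.
#' @export
run_config <- function(sim = sim_config(),
                       qc = qc_thresholds(),
                       ls = ls_params(),
                       meta = meta_params(),
                       bins = af_bins(),
                       varld = varld_config(window_size = 20L),
                       n_target = 50L,
                       array_density = 70L,
                       array_maf_floor = 0.05,
                       ld_r2_tag = 0.8,
                       impute_maf_floor = 0.01,
                       target_pops = NULL,
                       array_pops = NULL,
                       ref_pops = NULL,
                       do_meta = TRUE,
                       do_varld = TRUE,
                       switch_error_rate = 0,
                       seed = 1L,
                       out_dir = NULL) {
  pops <- names(sim$pops)
  if (is.null(target_pops)) target_pops <- pops[1L]
  if (is.null(array_pops)) array_pops <- pops
  if (is.null(ref_pops)) ref_pops <- pops
  stopifnot(all(target_pops %in% pops), all(array_pops %in% pops),
            all(ref_pops %in% pops))
  structure(list(sim = sim, qc = qc, ls = ls, meta = meta, bins = bins,
                 varld = varld, n_target = as.integer(n_target),
                 array_density = as.integer(array_density),
                 array_maf_floor = array_maf_floor, ld_r2_tag = ld_r2_tag,
                 impute_maf_floor = impute_maf_floor,
                 target_pops = target_pops, array_pops = array_pops,
                 ref_pops = ref_pops, do_meta = isTRUE(do_meta),
                 do_varld = isTRUE(do_varld),
                 switch_error_rate = switch_error_rate,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

.config_hash <- function(config) {
  cfg <- config; cfg$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)  # deterministic serialization of the config
  unname(tools::md5sum(f))
}

#' Run the full imputation-benchmark pipeline
#'
#' Chains simulate -> reference QC -> array design -> array masking ->
#' Li-Stephens imputation (one run per reference panel) ->
#' meta-imputation -> evaluation, plus a varLD scan between the first
#' two populations.  Each reference panel keeps only sites polymorphic
#' in its own samples after QC (a panel only "discovers" its own
#' variants), which is what gives meta-imputation its variant-yield
#' advantage.
#'
#' @param config a \code{\link{run_config}}.
#' @return List of class \code{pipeline_result} with \code{reports} (one
#'   \code{eval_report} per target x array x panel combination, names
#'   \code{"<target>.<array>.<panel>"}), \code{varld} (scan result or
#'   NULL), \code{artifacts} (data.frame of files written, empty when
#'   \code{out_dir} is NULL), \code{seed} and \code{config_hash}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- .config_hash(config)
  prov <- list(seed = config$seed, config_hash = hash)
  out_dir <- config$out_dir
  artifacts <- list()
  emit <- function(kind, name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    path <- file.path(out_dir, name)
    writer(path)
    artifacts[[length(artifacts) + 1L]] <<- data.frame(
      kind = kind, path = path, stringsAsFactors = FALSE)
    invisible(path)
  }

  sim <- config$sim
  sim$seed <- config$seed
  panels <- simulate_populations(sim)
  pops <- names(panels)

  splits <- list()
  for (i in seq_along(pops)) {
    splits[[pops[i]]] <- split_reference_target(
      panels[[pops[i]]], config$n_target, seed = config$seed + 1000L + i)
  }

  refs <- list()
  for (p in config$ref_pops) {
    qcres <- apply_qc_cascade(splits[[p]]$reference, thresholds = config$qc)
    ref <- qcres$panel
    poly <- ref$sites$af > 0 & ref$sites$af < 1    # panel-discovered sites
    refs[[p]] <- subset_sites(ref, poly)
    emit("reference_vcf", paste0("ref_", p, ".vcf"), function(f)
      write_panel_vcf(refs[[p]], f, prov))
    emit("qc_report", paste0("qc_", p, ".json"), function(f)
      jsonlite::write_json(unclass(qcres$report), f, auto_unbox = TRUE,
                           pretty = TRUE))
  }

  arrays <- list()
  for (p in config$array_pops) {
    arrays[[p]] <- design_array(splits[[p]]$reference, config$array_density,
                                config$array_maf_floor, config$ld_r2_tag,
                                design_pop = p)
    emit("manifest", paste0("array_", p, ".tsv"), function(f)
      write_manifest_tsv(arrays[[p]], f))
  }

  reports <- list()
  for (tp in config$target_pops) {
    truth <- splits[[tp]]$target
    for (ap in config$array_pops) {
      typed <- mask_to_array(truth, arrays[[ap]],
                             maf_floor = config$impute_maf_floor)
      tg <- phase_targets(truth, typed,
                          switch_rate = config$switch_error_rate,
                          seed = config$seed + 2000L)
      emit("typed_vcf", paste0("typed_", tp, "_", ap, ".vcf"), function(f)
        write_panel_vcf(typed, f, prov))
      dsets <- list()
      for (rp in config$ref_pops) {
        d <- impute(tg, refs[[rp]], config$ls, panel_id = rp)
        dsets[[rp]] <- d
        key <- paste(tp, ap, rp, sep = ".")
        reports[[key]] <- evaluate_imputation(d, truth, config$bins)
        emit("dosage_vcf", paste0("dos_", tp, "_", ap, "_", rp, ".vcf"),
             function(f) write_dosage_vcf(
               d, f, sub("\\.vcf$", "_emp.vcf", f), prov))
      }
      if (config$do_meta && length(dsets) >= 2L) {
        md <- meta_combine(dsets, tg, config$meta)
        key <- paste(tp, ap, "meta", sep = ".")
        reports[[key]] <- evaluate_imputation(md, truth, config$bins)
        emit("meta_vcf", paste0("meta_", tp, "_", ap, ".vcf"), function(f)
          write_dosage_vcf(md, f, NULL, prov))
      }
    }
  }

  varld_res <- NULL
  if (config$do_varld && length(pops) >= 2L) {
    sc <- varld_scan(panels[[pops[1L]]], panels[[pops[2L]]], config$varld)
    varld_res <- standardize_and_call(sc, config$varld)
    emit("varld_tsv", "varld_windows.tsv", function(f)
      write.table(varld_res$windows, f, sep = "\t", quote = FALSE,
                  row.names = FALSE))
    emit("varld_bed", "varld_top_regions.bed", function(f)
      write.table(varld_res$regions, f, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE))
  }

  art <- if (length(artifacts) > 0L) do.call(rbind, artifacts) else
    data.frame(kind = character(0), path = character(0))
  res <- structure(list(reports = reports, varld = varld_res,
                        artifacts = art, seed = config$seed,
                        config_hash = hash),
                   class = "pipeline_result")
  emit("report_json", "eval_reports.json", function(f)
    write_reports_json(res, f))
  res$artifacts <- if (length(artifacts) > 0L) do.call(rbind, artifacts) else art
  res
}

#' Serialize pipeline evaluation reports as stable JSON
#'
#' @param result a \code{pipeline_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_reports_json <- function(result, path) {
  payload <- list(
    seed = result$seed,
    config_hash = result$config_hash,
    reports = lapply(result$reports, function(r)
      list(panel_id = r$panel_id, per_bin = r$per_bin,
           overall_mean_r2 = r$overall_mean_r2,
           n_excluded_zero_var = r$n_excluded_zero_var,
           total_imputed = r$total_imputed,
           total_well_imputed = r$total_well_imputed)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d evaluation reports (seed %d, config %s)\n",
              length(x$reports), x$seed, x$config_hash))
  for (nm in names(x$reports))
    cat(sprintf("  %-24s overall mean R2 = %.4f\n", nm,
                x$reports[[nm]]$overall_mean_r2))
  if (!is.null(x$varld))
    cat(sprintf("  varLD: %d windows, %d region(s) above the top-%g%% threshold\n",
                nrow(x$varld$windows), nrow(x$varld$regions), 1))
  invisible(x)
}
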