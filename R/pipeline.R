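#' Pipeline configuration
#'
#' Bundles all stage parameters with the simulation config. Defaults
#' mirror the analysis conventions used throughout the package: 200-bp
#' windows stepped by half a window, |fold-change| > 2 with FDR < 0.05
#' for differential calls, top-200/600 opening regions for outlier QC,
#' LOWESS span 0.02 for profiles, and adjusted p < 1e-3 for enrichment.
#'
#' @param seed Integer seed propagated to the simulation.
#' @param sim A [sim_config()] (rebuilt with `seed` when omitted).
#' @param window_bp,step Differential window size and step (bp).
#' @param fc_min,fdr_max Differential-call thresholds.
#' @param top_n Region-list depths for outlier QC.
#' @param lowess_span Aggregate-profile smoothing span.
#' @param peak_p Poisson threshold of the peak caller.
#' @param es_alpha Enrichment significance threshold (adjusted p).
#' @param write_tracks Also write per-sample cut-site BED files (large;
#'   default `FALSE`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            window_bp = 200L, step = window_bp %/% 2L,
                            fc_min = 2, fdr_max = 0.05,
                            top_n = c(200L, 600L), lowess_span = 0.02,
                            peak_p = 1e-5, es_alpha = 1e-3,
                            write_tracks = FALSE) {
  structure(list(seed = as.integer(seed), sim = sim, window_bp = window_bp,
                 step = step, fc_min = fc_min, fdr_max = fdr_max,
                 top_n = top_n, lowess_span = lowess_span, peak_p = peak_p,
                 es_alpha = es_alpha, write_tracks = write_tracks),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror [pipeline_config()] arguments; keys under `sim` are
#' passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  raw$sim <- NULL
  seed <- if (!is.null(raw$seed)) raw$seed else 1L
  if (!is.null(sim_args)) {
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    if (!is.null(sim_args$genome)) sim_args$genome <- unlist(sim_args$genome)
    if (!is.null(sim_args$n_dhs)) sim_args$n_dhs <- unlist(sim_args$n_dhs)
    raw$sim <- do.call(sim_config, sim_args)
  }
  do.call(pipeline_config, raw)
}

.pipeline_stages <- c("simulate", "diff", "classify", "profile",
                      "annotate", "geneclass", "enrich")

.require_state <- function(state, keys, needed_stage) {
  miss <- keys[!vapply(keys, function(k) !is.null(state[[k]]), TRUE)]
  if (length(miss))
    stop("missing outputs (", paste(miss, collapse = ", "),
         "); run stage '", needed_stage, "' first")
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# map simulation truth classes to the catalog's prior sex-bias
# designation (sex bias is an input annotation, as in the reference
# analysis; only the pulse response is inferred from the data)
.class_to_sexbias <- function(class) {
  c(dynamic_male = "male", static_male = "male",
    static_female = "female", dynamic_indep = "independent",
    background = "independent")[class]
}

#' Run the analysis pipeline end-to-end on simulated data
#'
#' Executes the stages `simulate`, `diff` (windowed differential test
#' with outlier rejection and re-test), `classify` (pulse-response and
#' sex-bias cross-classification), `profile` (aggregate cut-site
#' profiles), `annotate` (target genes, chromatin states, STAT5
#' binding), `geneclass` (sex-biased gene hypox classes) and `enrich`
#' (batch enrichment scores) in dependency order, writing TSV/BED
#' artifacts and a manifest of MD5 content hashes to `outdir`. Re-running
#' with the same config yields identical hashes.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run (default all, in
#'   order). Requesting a stage whose inputs have not been produced (in
#'   this call or via `state`) is an error naming the stage to run first.
#' @param outdir Output directory (created if needed).
#' @param state Optional state list from a previous call, to resume.
#' @return List with `state` (all in-memory stage products), `manifest`
#'   (data frame of written files and MD5 hashes) and `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = .pipeline_stages,
                         outdir = file.path(tempdir(), "pulseDHS_run"),
                         state = list()) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(x, name) {
    files[[name]] <<- .write_tsv(x, file.path(outdir, name))
  }

  for (stage in stages) {
    switch(stage,
      simulate = {
        ann <- simulate_annotations(config$sim)
        sim <- simulate_cut_tracks(config$sim, ann)
        expr <- simulate_expression(config$sim, ann)
        state$ann <- ann
        state$tracks <- sim$tracks
        state$samples <- sim$samples
        state$expr <- expr
        write_bed(ann$dhs, file.path(outdir, "dhs_catalog.bed"))
        files[["dhs_catalog.bed"]] <- file.path(outdir, "dhs_catalog.bed")
        put(ann$truth$dhs, "truth_dhs.tsv")
        put(ann$truth$genes, "truth_genes.tsv")
        put(ann$genes, "genes.tsv")
        put(ann$tads, "tads.tsv")
        put(sim$samples, "samples.tsv")
        put(expr, "expression.tsv")
        if (isTRUE(config$write_tracks)) {
          for (id in names(sim$tracks)) {
            tr <- sim$tracks[[id]]
            cut_bed <- do.call(rbind, lapply(names(tr$cuts), function(chr)
              data.frame(chrom = chr, start = tr$cuts[[chr]]$pos,
                         end = tr$cuts[[chr]]$pos + 1L, name = ".",
                         score = tr$cuts[[chr]]$count, strand = ".")))
            nm <- paste0("cuts_", id, ".bed")
            write_bed(cut_bed, file.path(outdir, nm))
            files[[nm]] <- file.path(outdir, nm)
          }
        }
        message("simulate: ", nrow(ann$dhs), " DHS, ",
                length(sim$tracks), " samples")
      },
      diff = {
        .require_state(state, c("tracks", "samples"), "simulate")
        male <- state$samples$group %in% c("high", "low")
        tracks_m <- state$tracks[state$samples$sample_id[male]]
        groups <- state$samples$group[male]
        genome <- config$sim$genome
        peaks <- lapply(tracks_m, function(tr)
          call_peaks(tr, genome, window_bp = config$window_bp,
                     p_threshold = config$peak_p))
        union <- merge_intervals(do.call(rbind, peaks))
        wc <- window_counts(tracks_m, genome, config$window_bp, config$step)
        ws <- test_windows(wc, groups)
        regions <- call_differential_regions(ws, config$fc_min,
                                             config$fdr_max, union)
        qc <- detect_outliers(regions, tracks_m, groups, config$top_n)
        keep <- !qc$flagged
        message("diff: ", sum(!keep), " outlier sample(s) flagged")
        if (any(!keep)) {
          wc <- window_counts(tracks_m[keep], genome, config$window_bp,
                              config$step)
          ws <- test_windows(wc, groups[keep])
          regions <- call_differential_regions(ws, config$fc_min,
                                               config$fdr_max, union)
        }
        state$peak_union <- union
        state$window_stats <- ws
        state$regions <- regions
        state$qc <- qc
        write_bed(union, file.path(outdir, "peak_union.bed"))
        files[["peak_union.bed"]] <- file.path(outdir, "peak_union.bed")
        put(ws, "window_stats.tsv")
        put(regions, "differential_regions.tsv")
        put(qc, "qc_outliers.tsv")
        message("diff: ", sum(regions$direction == "up_in_A"),
                " opening and ", sum(regions$direction == "up_in_B"),
                " closing regions")
      },
      classify = {
        .require_state(state, c("ann", "regions"), "diff")
        dhs <- state$ann$dhs
        up_hi <- state$regions[state$regions$direction == "up_in_A", ]
        up_lo <- state$regions[state$regions$direction == "up_in_B", ]
        response <- label_response(dhs, up_hi, up_lo)
        sex_bias <- unname(.class_to_sexbias(state$ann$truth$dhs$class))
        cc <- cross_classify(sex_bias, response, names = dhs$name)
        state$response <- response
        state$sex_bias <- sex_bias
        state$classes <- cc
        tab <- dhs_annotation_table(dhs, sex_bias, response)
        put(tab, "dhs_classification.tsv")
        put(summarize_classes(cc$counts), "class_summary.tsv")
        message("classify: ", paste(names(cc$counts), as.integer(cc$counts),
                                    sep = "=", collapse = ", "))
      },
      profile = {
        .require_state(state, c("tracks", "samples", "classes"), "classify")
        genome <- config$sim$genome
        dhs <- state$ann$dhs
        pooled <- list(
          high = pool_tracks(state$tracks[state$samples$sample_id[
            state$samples$group == "high"]]),
          low = pool_tracks(state$tracks[state$samples$sample_id[
            state$samples$group == "low"]]))
        sets <- list(
          dynamic_male = dhs[state$classes$labels == "dynamic_male", ],
          static_indep = dhs[state$classes$labels == "static_indep", ])
        profs <- list()
        for (set_nm in names(sets)) {
          if (nrow(sets[[set_nm]]) == 0L) next
          win <- center_windows(sets[[set_nm]], genome)
          for (grp in names(pooled)) {
            pr <- aggregate_profile(pooled[[grp]], win, dhs,
                                    span = config$lowess_span)
            profs[[paste(set_nm, grp, sep = ".")]] <- pr
            nm <- paste0("profile_", set_nm, "_", grp, ".tsv")
            write_profile(pr, file.path(outdir, nm))
            files[[nm]] <- file.path(outdir, nm)
          }
        }
        state$profiles <- profs
        if (!is.null(profs[["dynamic_male.high"]])) {
          state$peak_ratio <- profs[["dynamic_male.high"]]$peak_value /
            profs[["dynamic_male.low"]]$peak_value
          message("profile: dynamic male-biased peak ratio high/low = ",
                  round(state$peak_ratio, 2))
        }
      },
      annotate = {
        .require_state(state, c("ann"), "simulate")
        dhs <- state$ann$dhs
        state$target_gene <- assign_target_gene(dhs, state$ann$genes,
                                                state$ann$tads)
        state$state_m <- assign_chrom_state(dhs, state$ann$states$M)
        state$state_f <- assign_chrom_state(dhs, state$ann$states$F)
        state$bound <- label_bound(dhs, state$ann$tf_peaks)
        ann_tab <- dhs_annotation_table(
          dhs, state$sex_bias %||% rep(NA, nrow(dhs)),
          state$response %||% rep(NA, nrow(dhs)),
          stat5_bound = state$bound,
          motif_count = state$ann$truth$dhs$motif_count,
          state_m = state$state_m, state_f = state$state_f,
          target_gene = state$target_gene)
        state$annotation <- ann_tab
        put(ann_tab, "dhs_annotation.tsv")
        message("annotate: ", sum(state$bound), " DHS STAT5-bound")
      },
      geneclass = {
        .require_state(state, c("expr"), "simulate")
        sb <- call_sex_bias(state$expr)
        hc <- call_hypox_class(state$expr, sb)
        labels <- data.frame(gene_id = state$expr$gene_id, sex_bias = sb,
                             hc, stringsAsFactors = FALSE)
        state$gene_labels <- labels
        put(labels, "gene_classes.tsv")
        put(tabulate_classes(sb, hc$hypox_class), "gene_class_summary.tsv")
        message("geneclass: ", sum(sb == "male"), " male-biased, ",
                sum(sb == "female"), " female-biased genes")
      },
      enrich = {
        .require_state(state, c("classes", "bound"), "annotate")
        dhs <- state$ann$dhs
        ids <- dhs$name
        lab <- state$classes$labels
        fg <- list(dynamic_male = ids[lab == "dynamic_male"],
                   static_male = ids[lab == "static_male"],
                   static_female = ids[lab == "static_female"])
        fg <- fg[vapply(fg, length, 1L) > 0]
        bg <- ids[lab == "static_indep"]
        feats <- list(stat5_bound = ids[state$bound],
                      stat5_motif = ids[state$ann$truth$dhs$motif_count > 0],
                      state_e6_male = ids[state$state_m == "E6"])
        res <- enrich_batch(fg, feats, bg, variant = "pct",
                            alpha = config$es_alpha)
        state$enrichment <- res
        put(res, "enrichment.tsv")
        message("enrich: ", sum(res$significant), " of ", nrow(res),
                " tests significant")
      })
  }
  manifest <- data.frame(file = names(files),
                         md5 = unname(tools::md5sum(unlist(files))),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  .write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  list(state = state, manifest = manifest, outdir = outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
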