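#' Validate a run configuration
#'
#' A run configuration (typically read from YAML with
#' [read_run_config()]) describes the inputs and the control structure
#' of a study:
#' * `reference`, `gff`, `chrom_sizes` (+ optional `cs_bed`,
#'   `centromere_bed`, `hot_bed`): annotation inputs;
#' * `samples`: a list of entries with `path`, `sample_id`, `genotype`,
#'   `treatment`, `replicate`;
#' * optional parameter blocks `filter`, `match`, `repair`, `origin`;
#' * `out_dir`, optional `seed`.
#'
#' Control completeness is enforced from the experimental design:
#' a treated WT sample requires at least one untreated WT sample (the
#' pedigree); a treated mutant sample requires an untreated sample of
#' the same genotype *and* a WT sample under the same treatment.
#'
#' @param config A named list.
#' @return The validated config (class `sv_run_config`), with parameter
#'   blocks materialized as parameter objects.
#' @export
validate_config <- function(config) {
  req <- c("reference", "gff", "chrom_sizes", "samples", "out_dir")
  missing_keys <- setdiff(req, names(config))
  if (length(missing_keys) > 0)
    stop("configuration missing keys: ",
         paste(missing_keys, collapse = ", "))
  for (p in c("reference", "gff", "chrom_sizes", "cs_bed",
              "centromere_bed", "hot_bed")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      stop("unreadable path for '", p, "': ", config[[p]])
  }
  ids <- vapply(config$samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", ids[duplicated(ids)][1])
  meta <- data.frame(
    sample_id = ids,
    genotype = vapply(config$samples, `[[`, character(1), "genotype"),
    treatment = vapply(config$samples, `[[`, character(1), "treatment"),
    path = vapply(config$samples, `[[`, character(1), "path"),
    stringsAsFactors = FALSE)
  bad_g <- setdiff(unique(meta$genotype), GENOTYPES)
  if (length(bad_g) > 0) stop("unknown genotype: ", bad_g[1])
  bad_t <- setdiff(unique(meta$treatment), TREATMENTS)
  if (length(bad_t) > 0) stop("unknown treatment: ", bad_t[1])
  for (p in meta$path)
    if (!file.exists(p)) stop("unreadable sample VCF: ", p)
  treated <- meta[meta$treatment != "none", , drop = FALSE]
  for (i in seq_len(nrow(treated))) {
    g <- treated$genotype[i]; t <- treated$treatment[i]
    if (!any(meta$genotype == g & meta$treatment == "none"))
      stop("missing control: no untreated ", g, " sample for treated ",
           treated$sample_id[i])
    if (g != "WT" &&
        !any(meta$genotype == "WT" & meta$treatment == t))
      stop("missing control: no WT ", t, " sample for treated mutant ",
           treated$sample_id[i])
  }
  config$filter <- do.call(filter_params,
                           as.list(config$filter %||% list()))
  config$match <- do.call(match_params, as.list(config$match %||% list()))
  config$repair <- do.call(repair_params,
                           as.list(config$repair %||% list()))
  config$origin <- do.call(origin_params,
                           as.list(config$origin %||% list()))
  config$seed <- as.integer(config$seed %||% 1L)
  class(config) <- "sv_run_config"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a YAML run configuration
#'
#' @param path YAML file path; relative file paths inside it are
#'   resolved against the YAML's directory.
#' @return The validated `sv_run_config`.
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) if (!is.null(p) && !file.exists(p) &&
                         file.exists(file.path(base, p)))
    file.path(base, p) else p
  for (k in c("reference", "gff", "chrom_sizes", "cs_bed",
              "centromere_bed", "hot_bed"))
    config[[k]] <- fix(config[[k]])
  config$samples <- lapply(config$samples, function(s) {
    s$path <- fix(s$path); s })
  validate_config(config)
}

#' Assemble the report bundle from stage outputs
#'
#' Collects the per-stage results into one canonical, deterministic
#' structure mirroring the study's figure panels: SV-type distributions
#' and homogeneity tests, INDEL size tables and rank tests, the
#' replicate Venn partition, element/chromatin-state tables with
#' goodness-of-fit tests against the genome background, centromeric
#' and HOT fractions, TE-superfamily tables, insertion-origin matrices
#' and repair summaries with the microhomology bubble data.
#'
#' @param stages Named list with components `samples`, `filtering`,
#'   `venn`, `induced`, `distributions`, `size_tables`, `stats`,
#'   `repair`, `origins` (any may be `NULL`-free; missing names error).
#' @return The report (class `sv_report`), a plain list serializable to
#'   JSON.
#' @export
build_report <- function(stages) {
  req <- c("samples", "filtering", "venn", "induced", "distributions",
           "size_tables", "stats", "repair", "origins")
  miss <- setdiff(req, names(stages))
  if (length(miss) > 0)
    stop("missing stage output: ", paste(miss, collapse = ", "))
  structure(stages[req], class = "sv_report")
}

serialize_gof <- function(g) {
  if (is.null(g)) return(NULL)
  list(statistic = g$statistic, df = g$df, p_value = g$p_value,
       low_expected_warning = g$low_expected_warning)
}

#' Run the full analysis pipeline
#'
#' Executes the end-to-end workflow on a validated configuration:
#' parse and filter every sample VCF, pool the untreated WT replicates
#' into the pedigree reference, compute the three-replicate Venn
#' partition, subtract controls from each treated sample to isolate
#' induced SVs, annotate all call sets against the genome layers,
#' classify deletion repair signatures, trace insertion origins of the
#' induced sets, run the reporting statistics, and write the bundle
#' (TSV tables, `report.json`, and an md5 manifest) under
#' `config$out_dir`. Outputs are pure functions of (inputs, config),
#' so a rerun writes byte-identical files.
#'
#' @param config An `sv_run_config` (see [validate_config()]).
#' @return The `sv_report`, invisibly; attribute `"paths"` lists the
#'   written files.
#' @export
run_all <- function(config) {
  if (!inherits(config, "sv_run_config")) config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_genome_fasta(config$reference)
  ann <- load_annotation(config$gff, config$chrom_sizes,
                         cs_bed = config$cs_bed,
                         centromere_bed = config$centromere_bed,
                         hot_bed = config$hot_bed)
  # stage 1: ingest + filter
  callsets <- list(); filtering <- list()
  for (s in config$samples) {
    raw <- parse_sv_vcf(s$path, sample_id = s$sample_id,
                        genotype = s$genotype, treatment = s$treatment,
                        replicate = s$replicate %||% 1L)
    flt <- filter_calls(raw, config$filter)
    callsets[[s$sample_id]] <- flt
    filtering[[s$sample_id]] <-
      list(input = n_records(raw), retained = n_records(flt),
           rejections = as.list(attr(flt, "rejections")),
           skipped = as.list(attr(raw, "skipped")))
  }
  meta <- data.frame(
    sample_id = names(callsets),
    genotype = vapply(callsets, `[[`, character(1), "genotype"),
    treatment = vapply(callsets, `[[`, character(1), "treatment"),
    stringsAsFactors = FALSE)
  # stage 2: pedigree pool + Venn over the first three WT replicates
  ped_ids <- meta$sample_id[meta$genotype == "WT" &
                              meta$treatment == "none"]
  pedigree <- if (length(ped_ids) > 0)
    lapply(ped_ids, function(id) callsets[[id]]) else list()
  venn <- NULL
  if (length(pedigree) >= 3)
    venn <- venn_partition(pedigree[[1]], pedigree[[2]], pedigree[[3]],
                           config$match)
  # stage 3: induced SVs per treated sample
  induced <- list()
  for (i in which(meta$treatment != "none")) {
    cs <- callsets[[meta$sample_id[i]]]
    if (cs$genotype == "WT") {
      ind <- induced_sv_workflow(cs, pedigree, params = config$match)
    } else {
      untr <- meta$sample_id[meta$genotype == cs$genotype &
                               meta$treatment == "none"]
      wt_tr <- meta$sample_id[meta$genotype == "WT" &
                                meta$treatment == cs$treatment]
      ind <- induced_sv_workflow(
        cs, lapply(untr, function(id) callsets[[id]]),
        wt_treated = if (length(wt_tr) > 0) callsets[[wt_tr[1]]],
        params = config$match)
    }
    induced[[cs$sample_id]] <- ind
  }
  # stage 4: annotation + sizes + repair for every call set,
  # origins for induced sets
  distributions <- list(); sizes <- list(); repair <- list()
  analysis_sets <- c(callsets,
                     setNames(induced,
                              paste0(names(induced), ".induced")))
  for (nm in names(analysis_sets)) {
    cs <- analysis_sets[[nm]]
    distributions[[nm]] <- element_distribution(cs, ann)
    sizes[[nm]] <- size_table(cs)
    repair[[nm]] <- repair_summary(cs, genome, config$repair)
  }
  origins <- list()
  for (nm in names(induced))
    origins[[nm]] <- origin_summary(induced[[nm]], genome, ann,
                                    config$origin)
  # stage 5: statistics
  stats_out <- list()
  if (length(ped_ids) >= 2) {
    tab <- t(vapply(ped_ids, function(id)
      as.integer(table(factor(callsets[[id]]$records$sv_type,
                              levels = SV_TYPES))),
      integer(length(SV_TYPES))))
    colnames(tab) <- SV_TYPES
    keep <- colSums(tab) > 0
    stats_out$sv_type_homogeneity_replicates <-
      serialize_gof(chisq_homogeneity(tab[, keep, drop = FALSE]))
  }
  for (nm in names(distributions)) {
    d <- distributions[[nm]]
    obs <- d$element_counts
    if (sum(obs) > 0)
      stats_out[[paste0("element_vs_genome.", nm)]] <-
        serialize_gof(chisq_gof(obs, d$background_bp[names(obs)]))
  }
  untreated_indel <- unlist(lapply(pedigree, function(cs)
    cs$records$length[cs$records$sv_type %in% c("DEL", "INS")]))
  for (nm in names(induced)) {
    x <- induced[[nm]]$records
    x <- x$length[x$sv_type %in% c("DEL", "INS")]
    if (length(x) > 0 && length(untreated_indel) > 0) {
      mw <- mann_whitney(x, untreated_indel)
      stats_out[[paste0("indel_size_vs_untreated.", nm)]] <-
        list(u_statistic = mw$u_statistic, p_value = mw$p_value,
             n1 = mw$n1, n2 = mw$n2)
    }
  }
  report <- build_report(list(
    samples = lapply(seq_len(nrow(meta)), function(i)
      c(as.list(meta[i, ]),
        n_filtered = n_records(callsets[[meta$sample_id[i]]]))),
    filtering = filtering,
    venn = if (is.null(venn)) NULL else
      list(region_counts = as.list(venn$region_counts),
           n_components = venn$n_components,
           n_inconsistent = venn$n_inconsistent),
    induced = lapply(induced, function(x)
      list(n = n_records(x),
           by_type = as.list(table(factor(x$records$sv_type,
                                          levels = SV_TYPES))),
           provenance = attr(x, "provenance"))),
    distributions = lapply(distributions, function(d)
      list(element_counts = as.list(d$element_counts),
           type_by_element = as.data.frame(as.table(d$type_by_element)),
           superfamily_counts = as.list(d$superfamily_counts),
           cs_counts = as.list(d$cs_counts),
           cs_grouped = as.list(d$cs_grouped),
           centromeric_fraction = d$centromeric_fraction,
           hot_count = d$hot_count, hot_fraction = d$hot_fraction,
           background_bp = as.list(d$background_bp))),
    size_tables = lapply(sizes, function(s)
      s[, c("sv_type", "n", "median", "q1", "q3")]),
    stats = stats_out,
    repair = lapply(repair, function(r)
      list(counts = as.list(r$counts), fractions = as.list(r$fractions),
           mh_histogram = as.list(r$mh_histogram),
           n_deletions = r$n_deletions)),
    origins = lapply(origins, function(o)
      list(matrix = as.data.frame(as.table(o$matrix)),
           status_counts = as.list(o$status_counts),
           intrachromosomal_fraction = o$intrachromosomal_fraction,
           truncated_te_count = o$truncated_te_count))))
  paths <- write_report_bundle(report, config, callsets, induced,
                               distributions, repair, origins, venn)
  attr(report, "paths") <- paths
  invisible(report)
}

write_report_bundle <- function(report, config, callsets, induced,
                                distributions, repair, origins, venn) {
  out <- config$out_dir
  paths <- character(0)
  wjson <- file.path(out, "report.json")
  jsonlite::write_json(unclass(report), wjson, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  paths <- c(paths, wjson)
  wtsv <- function(df, name) {
    p <- file.path(out, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  for (nm in names(distributions))
    wtsv(distributions[[nm]]$assignments,
         paste0("assignments.", nm, ".tsv"))
  for (nm in names(repair))
    if (nrow(repair[[nm]]$classifications) > 0)
      wtsv(repair[[nm]]$classifications, paste0("repair.", nm, ".tsv"))
  for (nm in names(origins))
    if (nrow(origins[[nm]]$origins) > 0)
      wtsv(origins[[nm]]$origins, paste0("origins.", nm, ".tsv"))
  for (nm in names(induced)) {
    aud <- attr(induced[[nm]], "audit")
    if (!is.null(aud) && nrow(aud) > 0)
      wtsv(aud, paste0("subtraction_audit.", nm, ".tsv"))
    wtsv(induced[[nm]]$records, paste0("induced.", nm, ".tsv"))
  }
  if (!is.null(venn))
    wtsv(data.frame(region = names(venn$region_counts),
                    count = as.integer(venn$region_counts)),
         "venn_regions.tsv")
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  mpath <- file.path(out, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(paths, mpath)
}
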