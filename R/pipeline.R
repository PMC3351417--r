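#' End-to-end analysis run
#'
#' Orchestrates the full workflow on either a simulated dataset or real
#' input tables: quantification (RPKM, expression filters), both
#' differential-expression routes for D vs N with their top-100 overlap,
#' the Delta-I splicing scan for each treated-vs-normal contrast, the
#' drug-response classification, and the splice-event response comparison.
#' Exactly one of `sim` and `inputs` must be supplied.
#'
#' Each stochastic stage receives a seed derived deterministically from the
#' master seed (fixed offsets per stage), so reruns are byte-identical.
#'
#' @param sim A [sim_config()]; its seed is the master seed.
#' @param inputs A list of paths for a real dataset: `annotation` (refFlat),
#'   `transcript_counts`, `exon_counts`, `junction_counts`, `catalog`,
#'   `design`, optional named `lib_sizes` (defaults to transcript-count
#'   column sums), and `seed`.
#' @param rpkm_filter Transcript-route expression filter (default 1.0).
#' @param gene_rpkm_filter Gene-route filter (default 0.5).
#' @param splice_rpkm_cutoff Expression gate for splicing (default 3.0).
#' @param fc_cutoff,p_cutoff,fdr_cutoff,delta_cutoff Route cutoffs
#'   (defaults 1.5, 0.05, 0.25, 0.2).
#' @param combine ANOVA-route rule combining fold and p cutoffs.
#' @param top_n Size of the compared top lists (default 100).
#' @param out_dir If not `NULL`, write all result tables and the run
#'   manifest there as TSV/JSON.
#' @return A list with `rpkm`, `de_anova`, `de_sam`, `overlap`, `events`
#'   (one `splice_scan` per contrast), `calls`, `splice_sets`, `truth` (for
#'   simulated runs) and `manifest`.
#' @export
run_pipeline <- function(sim = NULL, inputs = NULL,
                         rpkm_filter = 1.0, gene_rpkm_filter = 0.5,
                         splice_rpkm_cutoff = 3.0, fc_cutoff = 1.5,
                         p_cutoff = 0.05, fdr_cutoff = 0.25,
                         delta_cutoff = 0.2, combine = c("and", "or"),
                         top_n = 100, out_dir = NULL) {
  combine <- arg_match(combine)
  if (is.null(sim) == is.null(inputs)) {
    abort("supply exactly one of `sim` (simulation config) or `inputs` (real data paths)")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  if (!is.null(sim)) {
    master_seed <- sim$seed
    ds <- stage("simulate", simulate_dataset(sim))
  } else {
    master_seed <- as.integer(inputs$seed %||% 1L)
    ds <- stage("load", load_pipeline_inputs(inputs))
  }
  seeds <- c(sam = master_seed + 101L, splicing = master_seed + 211L)
  models <- ds$models; catalog <- ds$catalog; design <- ds$design
  counts <- ds$counts

  quant <- stage("quantify", {
    lens <- exon_model_lengths(models)
    tx_rpkm <- rpkm(counts$transcript,
                    setNames(lens$length, lens$transcript_id),
                    counts$lib_sizes)
    expressed <- filter_expressed(tx_rpkm, rpkm_filter)
    ex_tbl <- exon_table(models)
    exon_rpkm <- rpkm(counts$exon, setNames(ex_tbl$length, ex_tbl$exon_id),
                      counts$lib_sizes)
    # gene route: log2 of the average exon RPKM per gene
    gene_log <- gene_exon_summary(exon_rpkm, models, mode = "average")
    gene_rpkm <- unlog_transform(gene_log)
    gene_expressed <- filter_expressed(gene_rpkm, gene_rpkm_filter)
    list(tx_rpkm = tx_rpkm, expressed = expressed, exon_rpkm = exon_rpkm,
         gene_log = gene_log, gene_rpkm = gene_rpkm,
         gene_expressed = gene_expressed)
  })

  de_anova <- stage("diffexpr_anova", anova_de(
    quant$tx_rpkm %>% filter(.data$feature_id %in% quant$expressed) %>%
      set_expr_scale("rpkm"),
    design, contrast = c("D", "N"), fc_cutoff = fc_cutoff,
    p_cutoff = p_cutoff, combine = combine))

  de_sam <- stage("diffexpr_sam", sam_de(
    quant$gene_log %>% filter(.data$feature_id %in% quant$gene_expressed) %>%
      set_expr_scale("log2", offset = log_offset(quant$gene_log)),
    design, contrast = c("D", "N"), fc_cutoff = fc_cutoff,
    fdr_cutoff = fdr_cutoff, n_perm = "exhaustive",
    seed = unname(seeds["sam"])))

  overlap <- stage("overlap", {
    sam_by_gene <- tidy(de_sam) %>%
      mutate(feature_id = models$transcript_id[match(.data$feature_id,
                                                     models$gene_id)])
    top_n_overlap(tidy(de_anova), sam_by_gene, n = top_n)
  })

  contrasts <- list(D = c("D", "N"), D_T1 = c("D_T1", "N"),
                    D_T2 = c("D_T2", "N"))
  events <- stage("splicing", purrr::imap(contrasts, function(cc, nm) {
    aspire_scan(counts$junction, counts$exon, catalog,
                expr = quant$gene_rpkm, models = models, design = design,
                contrast = cc, rpkm_cutoff = splice_rpkm_cutoff,
                delta_cutoff = delta_cutoff, fdr_cutoff = fdr_cutoff,
                seed = unname(seeds["splicing"]))
  }))

  response <- stage("response", {
    f_d <- fold_change(quant$tx_rpkm, design, c("D", "N"))
    f_t1 <- fold_change(quant$tx_rpkm, design, c("D_T1", "N"))
    f_t2 <- fold_change(quant$tx_rpkm, design, c("D_T2", "N"))
    ok <- f_d$defined & f_t1$defined & f_t2$defined &
      is.finite(f_d$signed_log2) & is.finite(f_t1$signed_log2) &
      is.finite(f_t2$signed_log2)
    folds <- tibble(feature_id = f_d$feature_id[ok],
                    d_log2 = f_d$signed_log2[ok],
                    t1_log2 = f_t1$signed_log2[ok],
                    t2_log2 = f_t2$signed_log2[ok],
                    altered = f_d$ratio[ok] >= fc_cutoff |
                      f_t1$ratio[ok] >= fc_cutoff |
                      f_t2$ratio[ok] >= fc_cutoff)
    calls <- classify_response_table(folds, tau = fc_cutoff) %>%
      left_join(folds %>% select("feature_id", "altered"), by = "feature_id")
    list(folds = folds, calls = calls)
  })
  splice_sets <- stage("splice_sets",
                       splice_response_sets(events$D, events$D_T1,
                                            events$D_T2))

  manifest <- list(
    package = "diaretseq",
    master_seed = master_seed,
    stage_seeds = as.list(seeds),
    config_hash = rlang::hash(if (!is.null(sim)) unclass(sim) else inputs),
    thresholds = list(rpkm_filter = rpkm_filter,
                      gene_rpkm_filter = gene_rpkm_filter,
                      splice_rpkm_cutoff = splice_rpkm_cutoff,
                      fc_cutoff = fc_cutoff, p_cutoff = p_cutoff,
                      fdr_cutoff = fdr_cutoff, delta_cutoff = delta_cutoff,
                      combine = combine, top_n = top_n),
    rows = list(
      transcripts = nrow(counts$transcript),
      expressed_transcripts = length(quant$expressed),
      expressed_genes = length(quant$gene_expressed),
      de_anova = sum(de_anova$passes), de_sam = sum(de_sam$passes),
      overlap_shared = overlap$shared,
      events = purrr::map_int(events, ~ sum(.x$passes)),
      calls = nrow(response$calls)
    )
  )

  result <- list(rpkm = quant$tx_rpkm, gene_rpkm = quant$gene_rpkm,
                 de_anova = de_anova, de_sam = de_sam, overlap = overlap,
                 events = events, folds = response$folds,
                 calls = response$calls, splice_sets = splice_sets,
                 truth = ds$truth, manifest = manifest)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_results(quant$tx_rpkm, file.path(out_dir, "rpkm.tsv"))
    write_results(tidy(de_anova), file.path(out_dir, "de_anova.tsv"))
    write_results(tidy(de_sam), file.path(out_dir, "de_sam.tsv"))
    write_results(tidy(overlap), file.path(out_dir, "overlap.tsv"))
    purrr::iwalk(events, function(ev, nm) {
      write_results(tidy(ev), file.path(out_dir, paste0("events_", nm, "_vs_N.tsv")))
    })
    write_results(tibble(response$calls), file.path(out_dir, "calls.tsv"))
    write_results(splice_sets$membership,
                  file.path(out_dir, "splice_sets.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

load_pipeline_inputs <- function(inputs) {
  need <- c("annotation", "transcript_counts", "exon_counts",
            "junction_counts", "catalog", "design")
  missing_in <- setdiff(need, names(inputs))
  if (length(missing_in) > 0) {
    abort(paste0("inputs lack: ", paste(missing_in, collapse = ", ")))
  }
  models <- read_refflat(inputs$annotation)
  tx <- read_count_matrix(inputs$transcript_counts, integer_counts = TRUE)
  ex <- read_count_matrix(inputs$exon_counts, integer_counts = TRUE)
  jx <- read_junction_counts(inputs$junction_counts)
  lib <- inputs$lib_sizes %||% colSums(count_values(tx))
  list(models = models, catalog = read_pair_catalog(inputs$catalog),
       design = read_design(inputs$design),
       counts = list(transcript = tx, exon = ex, junction = jx,
                     lib_sizes = lib),
       truth = NULL)
}
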