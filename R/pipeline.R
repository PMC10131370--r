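#' Run the full ceRNA discovery workflow end to end
#'
#' Orchestrates the five stages — simulate (or load), differential
#' expression, ceRNA triad assembly, over-representation analysis, and
#' qPCR-style diagnostic validation — writing every stage's output and a run
#' manifest into `outdir`. Any stage failure aborts with an error naming the
#' stage. Re-running with the same config and seed reproduces the outputs
#' bit-identically.
#'
#' @param config a [sim_config()]; its seed drives every source of
#'   randomness.
#' @param outdir output directory (created if needed).
#' @param de_params a [de_params()]; defaults to the config's dispersion.
#' @param cerna_params a [cerna_params()].
#' @param top_pathway,top_go how many top enriched pathway / GO terms to
#'   export (defaults 20 and 10).
#' @param dataset optionally, an existing [simulate_dataset()] result to use
#'   instead of simulating (the `simulate` stage is then skipped).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with all stage results (`dataset`, `de`,
#'   `cerna`, `network`, `enrichment`, `validation`) and the `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         de_params = NULL, cerna_params = NULL,
                         top_pathway = 20L, top_go = 10L,
                         dataset = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(de_params)) de_params <- de_params(dispersion = config$dispersion)
  if (is.null(cerna_params)) cerna_params <- cernaflow::cerna_params()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[cernaflow] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_named("stage '", name, "' failed: ", conditionMessage(e)))
  }

  say("stage simulate")
  ds <- stage("simulate", {
    if (is.null(dataset)) dataset <- simulate_dataset(config)
    write_dataset(dataset, file.path(outdir, "data"))
    dataset
  })

  say("stage de")
  de <- stage("de", {
    out <- lapply(ds$matrices, call_de, design = ds$design, params = de_params)
    for (layer in names(out))
      write_tsv(de_table(out[[layer]]),
                file.path(outdir, paste0("de_", layer, ".tsv")))
    out
  })

  say("stage cerna")
  cr <- stage("cerna", {
    res <- assemble_triads(de, ds$interactions, ds$matrices, ds$design,
                           cerna_params)
    write_tsv(res$triads, file.path(outdir, "triads.tsv"))
    write_tsv(res$exclusions, file.path(outdir, "exclusions.tsv"))
    res
  })
  network <- stage("cerna", {
    net <- build_network(cr, de)
    write_network(net, file.path(outdir, "network"))
    net
  })

  say("stage enrich")
  enr <- stage("enrich", {
    query <- network$nodes$id[network$nodes$layer == "mRNA"]
    ann <- ds$annotations
    # each category has its own annotated background; genes without an
    # annotation in a category are dropped from that category's query
    # (explicitly counted, never silently inside the test itself)
    rows <- NULL
    n_query <- 0L
    for (cat in unique(ann$category)) {
      sel <- ann$category == cat
      sub <- annotation_set(ann$term_id[sel], ann$term_name[sel], cat,
                            ann$members[sel])
      q_cat <- intersect(query, unique(unlist(sub$members)))
      n_query <- max(n_query, length(q_cat))
      if (length(q_cat) == 0) next
      rows <- rbind(rows, hypergeom_enrich(q_cat, sub))
    }
    if (is.null(rows)) {
      say("no annotated network mRNAs; enrichment skipped")
    } else {
      write_tsv(rows, file.path(outdir, "enrichment.tsv"))
      tops <- rbind(top_terms(rows, "pathway", top_pathway),
                    top_terms(rows, "GO_BP", top_go),
                    top_terms(rows, "GO_MF", top_go),
                    top_terms(rows, "GO_CC", top_go))
      write_tsv(tops, file.path(outdir, "enrichment_top.tsv"))
    }
    list(rows = rows, n_query = n_query,
         n_unannotated = length(query) - n_query)
  })

  say("stage roc")
  val <- stage("roc", {
    if (nrow(ds$truth$validation) == 0) {
      list(ct = NULL, summary = NULL)
    } else {
      ct <- simulate_ct_table(config, ds$truth)
      write_ct_table(ct, file.path(outdir, "ct_table.tsv"))
      genes <- unique(ct$gene_id)
      summary <- do.call(rbind, lapply(genes, function(g) {
        fc <- ddct_fold_change(ct, g)
        roc <- diagnostic_roc(ct, g)
        data.frame(gene_id = g, mean_fold = fc$mean_fold, auc = roc$auc,
                   stringsAsFactors = FALSE)
      }))
      write_tsv(summary, file.path(outdir, "validation_summary.tsv"))
      list(ct = ct, summary = summary)
    }
  })

  de_counts <- lapply(de, function(x) {
    tab <- x$table
    list(total = sum(tab$is_de), up = sum(tab$direction == "up"),
         down = sum(tab$direction == "down"))
  })
  data_files <- list.files(file.path(outdir, "data"), full.names = TRUE)
  manifest <- list(
    tool = "cernaflow",
    version = as.character(utils::packageVersion("cernaflow")),
    seed = config$seed,
    rng = "Mersenne-Twister/Inversion/Rejection",
    config = unclass(config),
    input_digests = as.list(stats::setNames(unname(tools::md5sum(data_files)),
                                            basename(data_files))),
    stages = list(
      de = de_counts,
      cerna = list(candidates = nrow(cr$triads) + nrow(cr$exclusions),
                   surviving_triads = nrow(cr$triads),
                   network_nodes = nrow(network$nodes),
                   network_edges = nrow(network$edges)),
      enrich = list(query_mrnas = enr$n_query,
                    unannotated_dropped = enr$n_unannotated,
                    terms_tested = if (is.null(enr$rows)) 0L else nrow(enr$rows)),
      roc = list(genes_evaluated = if (is.null(val$summary)) 0L
                 else nrow(val$summary))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say(sprintf("done: %d/%d/%d DE (lncRNA/miRNA/mRNA), %d triads",
              de_counts$lncRNA$total, de_counts$miRNA$total,
              de_counts$mRNA$total, nrow(cr$triads)))
  invisible(list(dataset = ds, de = de, cerna = cr, network = network,
                 enrichment = enr, validation = val, manifest = manifest))
}
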