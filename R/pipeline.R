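# End-to-end orchestration: read and clean per-gene alignments, M0 fits and
# the dS filter, branch / site / branch-site tests with FDR per family, BEB
# site identification, amino-acid ancestral reconstruction and pair
# convergence, and the conservative intersection report.

#' Pipeline configuration
#'
#' Every analysis constant is a named, defaulted field. Thresholds:
#' dS filter 1.0, FDR level 0.05, BEB posterior probability 0.95, starting
#' omega values (0.5, 1, 2).
#'
#' @param genes_dir directory of per-gene alignments.
#' @param tree_file newick tree path.
#' @param class_map_file TSV gene -> functional class.
#' @param foregrounds character vector of foreground tip labels, each tested
#'   in turn.
#' @param convergence_pairs list of 2-vectors of tip labels.
#' @param exclusions genes excluded up front (e.g. visually ambiguous
#'   alignments); a user decision, not computed.
#' @param format alignment format, `"fasta"` or `"phylip"`.
#' @param ds_threshold maximum tolerated per-branch dS.
#' @param fdr_level FDR significance level.
#' @param pp_threshold BEB flagging threshold.
#' @param starts starting omega values for all fits.
#' @param convergence_mode `"pooled"` or `"separate"` Poisson testing.
#' @param aa_model empirical exchangeability model name or a PAML .dat path.
#' @param run_site_models fit the M8a/M8 pair per gene (the slowest stage).
#' @param run_concatenated also analyze per-class concatenations.
#' @param seed integer seed recorded in the run log.
#' @param out_dir optional output directory for TSV/JSON reports.
#' @param control optimizer settings passed to the fitters.
#' @return a validated config object (list).
#' @export
pipeline_config <- function(genes_dir, tree_file, class_map_file,
                            foregrounds = c("Chlamydomonas_ICEL",
                                            "Coccomyxa_subellipsoidea",
                                            "Chlorella_ArM0029B",
                                            "Dunaliella_salina"),
                            convergence_pairs = list(c("Chlamydomonas_ICEL",
                                                       "Dunaliella_salina")),
                            exclusions = character(),
                            format = c("fasta", "phylip"),
                            ds_threshold = 1.0, fdr_level = 0.05,
                            pp_threshold = 0.95, starts = c(0.5, 1, 2),
                            convergence_mode = c("pooled", "separate"),
                            aa_model = "cpREV",
                            run_site_models = TRUE, run_concatenated = TRUE,
                            seed = 1L, out_dir = NULL, control = list()) {
  format <- match.arg(format)
  convergence_mode <- match.arg(convergence_mode)
  stopifnot(ds_threshold > 0, fdr_level > 0, fdr_level < 1,
            pp_threshold > 0, pp_threshold <= 1, length(starts) >= 1)
  if (!dir.exists(genes_dir)) stop("configuration error: genes_dir not found: ", genes_dir)
  if (!file.exists(tree_file)) stop("configuration error: tree_file not found: ", tree_file)
  if (!file.exists(class_map_file)) stop("configuration error: class_map_file not found: ", class_map_file)
  structure(list(genes_dir = genes_dir, tree_file = tree_file,
                 class_map_file = class_map_file, foregrounds = foregrounds,
                 convergence_pairs = convergence_pairs,
                 exclusions = exclusions, format = format,
                 ds_threshold = ds_threshold, fdr_level = fdr_level,
                 pp_threshold = pp_threshold, starts = starts,
                 convergence_mode = convergence_mode, aa_model = aa_model,
                 run_site_models = run_site_models,
                 run_concatenated = run_concatenated,
                 seed = as.integer(seed), out_dir = out_dir,
                 control = control),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Relative paths are resolved against the YAML file's directory.
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(p)
    ifelse(file.exists(p) | dir.exists(p), p, file.path(base, p))
  }
  y$genes_dir <- resolve(y$genes_dir)
  y$tree_file <- resolve(y$tree_file)
  y$class_map_file <- resolve(y$class_map_file)
  if (!is.null(y$convergence_pairs) && !is.list(y$convergence_pairs[[1]])) {
    y$convergence_pairs <- lapply(y$convergence_pairs, function(p)
      strsplit(p, "\\s*,\\s*")[[1]])
  }
  do.call(pipeline_config, y)
}

.log_line <- function(log, ...) {
  c(log, paste0(format(Sys.time(), "%H:%M:%S"), "  ", ...))
}

#' Run the full positive-selection and convergence pipeline
#'
#' Stages: read + clean genes, M0 fit and dS filter, branch / site /
#' branch-site model pairs per foreground with LRT and BH FDR per family,
#' BEB sites on significant branch-site fits, amino-acid ancestral
#' reconstruction and pair convergence with the Poisson test and FDR, and
#' the intersection of positively selected and convergent genes. Individual
#' gene failures are recorded and skipped (fail-soft); the run is
#' deterministic given its configuration.
#'
#' @param config a `pipeline_config`.
#' @return object of class `report_bundle`: per-gene status table, M0/dS
#'   table, LRT tables per family, BEB table, convergence table,
#'   conservative gene list and the run log.
#' @export
run_pipeline <- function(config) {
  set.seed(config$seed)
  log <- character(0)
  log <- .log_line(log, "pipeline start, seed ", config$seed)
  files <- sort(list.files(config$genes_dir, full.names = TRUE,
                           pattern = "\\.(fa|fasta|fas|phy|phylip|txt)$"))
  if (length(files) == 0L) {
    stop("configuration error: no alignment files in ", config$genes_dir)
  }
  tree <- ape::read.tree(config$tree_file)
  class_map <- read_class_map(config$class_map_file)
  status <- data.frame(gene = character(0), status = character(0),
                       reason = character(0))
  genes <- list()
  for (f in files) {
    gname <- sub("\\.[^.]*$", "", basename(f))
    if (gname %in% config$exclusions) {
      status <- rbind(status, data.frame(gene = gname, status = "excluded",
                                         reason = "configured exclusion"))
      next
    }
    aln <- tryCatch(clean_alignment(read_gene_alignment(f, config$format)),
                    error = function(e) conditionMessage(e))
    if (is.character(aln)) {
      status <- rbind(status, data.frame(gene = gname, status = "failed",
                                         reason = aln))
      log <- .log_line(log, "FAILED read/clean ", gname, ": ", aln)
      next
    }
    genes[[gname]] <- aln
  }
  log <- .log_line(log, length(genes), " genes read")

  # M0 fits and the dS filter
  m0_fits <- list()
  for (g in names(genes)) {
    fit <- tryCatch(fit_m0(genes[[g]], tree, starts = config$starts,
                           control = config$control),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      status <- rbind(status, data.frame(gene = g, status = "failed",
                                         reason = fit))
      log <- .log_line(log, "FAILED M0 ", g, ": ", fit)
      genes[[g]] <- NULL
      next
    }
    m0_fits[[g]] <- fit
  }
  flt <- filter_genes_by_ds(m0_fits, config$ds_threshold)
  for (g in flt$retained) {
    status <- rbind(status, data.frame(gene = g, status = "analyzed",
                                       reason = ""))
  }
  if (nrow(flt$discarded)) {
    for (i in seq_len(nrow(flt$discarded))) {
      status <- rbind(status, data.frame(
        gene = flt$discarded$gene[i], status = "filtered",
        reason = paste0("max branch dS = ",
                        format(flt$discarded$max_ds[i], digits = 3),
                        " on ", flt$discarded$branch[i])))
    }
  }
  retained <- flt$retained
  log <- .log_line(log, length(retained), " genes pass the dS filter")
  m0_table <- do.call(rbind, lapply(m0_fits, function(f) data.frame(
    gene = f$dataset_id, lnL = f$loglik, kappa = f$params$kappa,
    omega = f$params$omega, tree_length = sum(f$branch_lengths),
    max_dS = suppressWarnings(max(f$per_branch_dNdS$dS, na.rm = TRUE)),
    retained = f$dataset_id %in% retained)))

  datasets <- genes[retained]
  if (config$run_concatenated && length(retained) > 1) {
    in_map <- retained[retained %in% names(class_map)]
    if (length(in_map)) {
      cats <- tryCatch(concatenate_by_class(genes[in_map], class_map),
                       error = function(e) NULL)
      if (!is.null(cats)) {
        names(cats) <- paste0("concat_", names(cats))
        datasets <- c(datasets, cats)
        log <- .log_line(log, "concatenated classes: ",
                         paste(names(cats), collapse = ", "))
      }
    }
  }

  # branch, site and branch-site tests; FDR families are one comparison
  # type x foreground over the gene-level datasets (concatenations form
  # their own family)
  lrt_tables <- list()
  bs_fits <- list()
  is_concat <- grepl("^concat_", names(datasets))
  fam_of <- function(nms) ifelse(grepl("^concat_", nms), "concat", "gene")
  for (fgx in config$foregrounds) {
    pairs <- list()
    for (d in names(datasets)) {
      res <- tryCatch(fit_branch_model(datasets[[d]], tree, fgx,
                                       starts = config$starts,
                                       control = config$control),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) {
        log <- .log_line(log, "FAILED branch ", d, "/", fgx, ": ", res)
        next
      }
      pairs[[d]] <- res
    }
    for (fam in unique(fam_of(names(pairs)))) {
      sel <- pairs[fam_of(names(pairs)) == fam]
      key <- paste0("branch|", fgx, "|", fam)
      lrt_tables[[key]] <- lrt_table(sel, comparison = key,
                                     alpha = config$fdr_level)
    }
  }
  if (config$run_site_models) {
    pairs <- list()
    for (d in names(datasets)) {
      res <- tryCatch(fit_site_models(datasets[[d]], tree,
                                      starts = config$starts,
                                      control = config$control),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) {
        log <- .log_line(log, "FAILED site models ", d, ": ", res)
        next
      }
      pairs[[d]] <- res
    }
    for (fam in unique(fam_of(names(pairs)))) {
      sel <- pairs[fam_of(names(pairs)) == fam]
      key <- paste0("M8vM8a|", fam)
      lrt_tables[[key]] <- lrt_table(sel, comparison = key,
                                     alpha = config$fdr_level)
    }
  }
  for (fgx in config$foregrounds) {
    pairs <- list()
    for (d in names(datasets)) {
      res <- tryCatch(fit_branch_site(datasets[[d]], tree, fgx,
                                      starts = config$starts,
                                      control = config$control),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) {
        log <- .log_line(log, "FAILED branch-site ", d, "/", fgx, ": ", res)
        next
      }
      pairs[[d]] <- res
      if (res$alt$boundary[["omega2"]]) {
        log <- .log_line(log, "omega2 at bound for ", d, "/", fgx)
      }
    }
    bs_fits[[fgx]] <- pairs
    for (fam in unique(fam_of(names(pairs)))) {
      sel <- pairs[fam_of(names(pairs)) == fam]
      key <- paste0("branch-site|", fgx, "|", fam)
      lrt_tables[[key]] <- lrt_table(sel, comparison = key,
                                     alpha = config$fdr_level)
    }
  }

  # BEB on significant branch-site alternatives (gene-level family)
  beb_table <- NULL
  psg <- character(0)
  for (fgx in names(bs_fits)) {
    key <- paste0("branch-site|", fgx, "|gene")
    tb <- lrt_tables[[key]]
    if (is.null(tb)) next
    for (d in tb$dataset[tb$significant]) {
      bb <- tryCatch(
        beb_sites(bs_fits[[fgx]][[d]]$alt, datasets[[d]], tree, fgx,
                  pp_threshold = config$pp_threshold),
        error = function(e) NULL)
      if (is.null(bb)) next
      hits <- bb[bb$flagged, , drop = FALSE]
      if (nrow(hits)) {
        psg <- union(psg, d)
        beb_table <- rbind(beb_table, data.frame(
          gene = d, foreground = fgx, site = hits$site,
          pp = hits$pp_positive,
          label = sprintf("%d-%.3f", hits$site, hits$pp_positive)))
      }
    }
  }
  log <- .log_line(log, "positively selected genes (BEB): ",
                   paste(sort(psg), collapse = ", "))

  # convergence analyses per pair over retained genes
  aa_ex <- if (file.exists(config$aa_model)) read_paml_dat(config$aa_model)
           else aa_exchangeabilities(config$aa_model)
  conv_tables <- list()
  conv_genes <- character(0)
  for (pair in config$convergence_pairs) {
    rows <- list()
    for (g in retained) {
      row <- tryCatch({
        aa <- translate_alignment(genes[[g]])
        model <- aa_rate_matrix(aa_ex$S, aa_frequencies(aa))
        asr <- reconstruct_ancestors(aa, tree, model, control = config$control)
        pc <- pair_convergence_test(asr, pair, mode = config$convergence_mode)
        data.frame(gene = g,
                   observed_parallel = pc$observed_parallel,
                   observed_convergent = pc$observed_convergent,
                   expected_parallel = pc$expected_parallel,
                   expected_convergent = pc$expected_convergent,
                   positions = paste(c(pc$parallel_sites$site,
                                       pc$convergent_sites$site), collapse = ";"),
                   aa_changes = paste(c(pc$parallel_sites$label,
                                        pc$convergent_sites$label), collapse = ";"),
                   p_value = pc$p_value)
      }, error = function(e) conditionMessage(e))
      if (is.character(row)) {
        log <- .log_line(log, "FAILED convergence ", g, ": ", row)
        next
      }
      rows[[g]] <- row
    }
    tb <- do.call(rbind, rows)
    if (!is.null(tb)) {
      tb$q_value <- fdr_bh(tb$p_value)
      tb$significant <- tb$q_value < config$fdr_level
      conv_genes <- union(conv_genes, tb$gene[tb$significant &
        (tb$observed_parallel + tb$observed_convergent >
           tb$expected_parallel + tb$expected_convergent)])
    }
    conv_tables[[paste(pair, collapse = "_vs_")]] <- tb
  }
  log <- .log_line(log, "convergent genes: ", paste(sort(conv_genes), collapse = ", "))

  conservative <- conservative_adaptive_genes(psg, conv_genes)
  log <- .log_line(log, "conservative adaptive genes: ",
                   paste(conservative, collapse = ", "))

  bundle <- structure(list(
    status = status, m0_table = m0_table, lrt_tables = lrt_tables,
    beb_table = beb_table, convergence_tables = conv_tables,
    positively_selected = sort(psg), convergent = sort(conv_genes),
    conservative = conservative, log = log, config = config),
    class = "report_bundle")
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle: ", sum(x$status$status == "analyzed"), " analyzed, ",
      sum(x$status$status == "filtered"), " filtered, ",
      sum(x$status$status == "excluded"), " excluded, ",
      sum(x$status$status == "failed"), " failed\n",
      "  positively selected: ", paste(x$positively_selected, collapse = ", "),
      "\n  convergent: ", paste(x$convergent, collapse = ", "),
      "\n  conservative adaptive: ", paste(x$conservative, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a report bundle as TSV/JSON files
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(tb, name) {
    if (!is.null(tb) && nrow(tb)) {
      utils::write.table(tb, file.path(dir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  wt(bundle$status, "gene_status.tsv")
  wt(bundle$m0_table, "m0_ds_table.tsv")
  for (nm in names(bundle$lrt_tables)) {
    wt(bundle$lrt_tables[[nm]], paste0("lrt_", gsub("[^A-Za-z0-9]+", "_", nm), ".tsv"))
  }
  wt(bundle$beb_table, "beb_sites.tsv")
  for (nm in names(bundle$convergence_tables)) {
    wt(bundle$convergence_tables[[nm]], paste0("convergence_", nm, ".tsv"))
  }
  jsonlite::write_json(list(
    positively_selected = bundle$positively_selected,
    convergent = bundle$convergent,
    conservative = as.character(bundle$conservative)),
    file.path(dir, "summary.json"), auto_unbox = FALSE)
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
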