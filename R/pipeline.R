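# Orchestration: one call runs simulate/read -> screen -> clades ->
# barcodes, writes every artifact plus a checksummed manifest, and is
# byte-reproducible under a fixed seed and config.

#' Pipeline run configuration
#'
#' Exactly one input mode: `"simulate"` (run the generator), or
#' `"genbank_dir"` / `"fasta_dir"` (read annotated records or per-gene
#' FASTA files from `input_dir`).
#'
#' @param mode Input mode.
#' @param input_dir Directory of `.gb`/`.gbk` files or `<gene>.fasta`
#'   files (modes other than simulate).
#' @param sim A [sim_config()] (simulate mode).
#' @param screening A [screening_config()].
#' @param bar_width,bar_height Barcode geometry for the SVG outputs.
#' @export
run_config <- function(mode = c("simulate", "genbank_dir", "fasta_dir"),
                       input_dir = NULL, sim = sim_config(),
                       screening = screening_config(),
                       bar_width = 3, bar_height = 100) {
  mode <- match.arg(mode)
  if (mode != "simulate" && is.null(input_dir))
    stop("input_dir required for mode ", mode, call. = FALSE)
  structure(list(mode = mode, input_dir = input_dir, sim = sim,
                 screening = screening, bar_width = bar_width,
                 bar_height = bar_height),
            class = "run_config")
}

input_error <- function(msg) {
  stop(structure(class = c("mitomarker_input_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# per-gene FASTA directory -> minimal records (genes laid end to end)
records_from_gene_fastas <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (length(files) == 0L) input_error("no FASTA files in " %+% dir)
  per_gene <- lapply(files, read_fasta)
  names(per_gene) <- normalize_gene_name(
    tools::file_path_sans_ext(basename(files)))
  accs <- sort(unique(unlist(lapply(per_gene, names))))
  lapply(stats::setNames(accs, accs), function(acc) {
    feats <- list(); pieces <- character(0); pos <- 1L
    for (g in names(per_gene)) {
      s <- per_gene[[g]][acc]
      if (is.na(s)) next
      feats[[length(feats) + 1L]] <- new_gene_feature(
        g, pos, pos + nchar(s) - 1L, "+", unname(s), kind = "CDS")
      pieces <- c(pieces, s); pos <- pos + nchar(s)
    }
    new_mitogenome(acc, "unknown organism", paste(pieces, collapse = ""),
                   feats, is_circular = FALSE)
  })
}

`%+%` <- function(a, b) paste0(a, b)

#' Run the full screening pipeline
#'
#' Stages: obtain records (simulate or read), screen candidate markers
#' against the concatenated-gene reference tree, assign zero-SNP clades
#' over the selected markers and report their SNPs against the standard,
#' then render the standard's marker barcodes. Every artifact is listed
#' in `manifest.json` with an md5 checksum; identical config and seed
#' give identical checksums.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a data.frame (file, md5).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)  # truncate

  # --- stage: input ------------------------------------------------------
  truth <- NULL
  if (config$mode == "simulate") {
    sim <- simulate_collection(config$sim)
    records <- sim$records
    truth <- sim$truth
    gdir <- file.path(out_dir, "genomes")
    dir.create(gdir, showWarnings = FALSE)
    for (r in records)
      write_genbank(r, file.path(gdir, r$accession %+% ".gbk"))
    newick_write(truth$true_tree, file.path(out_dir, "truth.nwk"))
    utils::write.table(truth$mutation_log,
                       file.path(out_dir, "mutations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("simulated %d records (seed %d)", length(records),
         config$sim$seed)
  } else if (config$mode == "genbank_dir") {
    files <- list.files(config$input_dir, pattern = "\\.(gb|gbk|genbank)$",
                        full.names = TRUE)
    records <- list()
    for (f in files) {
      r <- tryCatch(read_genbank(f), error = function(e) {
        logf("unparseable record %s: %s", basename(f), conditionMessage(e))
        NULL
      })
      if (!is.null(r)) records[[length(records) + 1L]] <- r
    }
    if (length(records) == 0L)
      input_error("no parseable GenBank records in " %+% config$input_dir)
    names(records) <- vapply(records, `[[`, "", "accession")
    logf("read %d GenBank records", length(records))
  } else {
    records <- records_from_gene_fastas(config$input_dir)
    logf("read %d taxa from per-gene FASTA files", length(records))
  }

  inv <- gene_inventory(records)
  utils::write.table(inv, file.path(out_dir, "gene_inventory.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: screen -----------------------------------------------------
  screen <- screen_markers(records, config$screening)
  utils::write.table(as.data.frame(screen),
                     file.path(out_dir, "marker_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(screen)))
    logf("%s: %s (%s)", screen$gene[i], screen$verdict[i], screen$reason[i])
  reference <- attr(screen, "reference_tree")
  newick_write(reference, file.path(out_dir, "reference.nwk"))
  for (g in names(attr(screen, "gene_trees")))
    newick_write(attr(screen, "gene_trees")[[g]],
                 file.path(out_dir, g %+% ".nwk"))

  sel <- selected_markers(screen)
  standard <- config$screening$reference_accession
  if (is.null(standard)) standard <- reference$tip.label[1]

  # --- stage: clades + barcodes -----------------------------------------
  if (length(sel) > 0L) {
    msas <- attr(screen, "msas")[sel]
    clades <- assign_clades(reference, msas, reference = standard)
    report <- snps_vs_standard(clades, standard, msas,
                               config$screening$scoring)
    utils::write.table(clades, file.path(out_dir, "clades.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report, file.path(out_dir, "clade_snps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    std_rec <- records[[which(vapply(records, `[[`, "", "accession") ==
                                standard)]]
    for (g in sel) {
      f <- extract_gene(std_rec, g)
      write_barcode_svg(f$sequence,
                        file.path(out_dir, "barcode_" %+% g %+% ".svg"),
                        bar_width = config$bar_width,
                        bar_height = config$bar_height)
      writeLines(sub("\n$", "", make_qr_payload(
        std_rec$accession, std_rec$organism, g, f$sequence)),
        file.path(out_dir, "qr_payload_" %+% g %+% ".txt"))
      logf("barcode written for %s (standard %s)", g, standard)
    }
  } else {
    logf("no marker selected; clade and barcode stages skipped")
  }

  # --- manifest ----------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}
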