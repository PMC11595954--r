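# GenBank flat-file reading/writing, gene extraction, FASTA round trip.
# Coordinates are 1-based inclusive at this interface, matching deposited
# records; any zero-based arithmetic stays inside this file.

# Synonym table for gene-symbol normalization. Deposited mitogenome records
# vary in case and naming ("cytb" vs "cob", "rnl" vs "rrnL").
GENE_SYNONYMS <- c(
  cytb = "cob", cob = "cob", "cyt-b" = "cob",
  atp6 = "atp6", atp8 = "atp8", atp9 = "atp9",
  cox1 = "cox1", coxi = "cox1", co1 = "cox1",
  cox2 = "cox2", coxii = "cox2", co2 = "cox2",
  cox3 = "cox3", coxiii = "cox3", co3 = "cox3",
  nad1 = "nad1", nad2 = "nad2", nad3 = "nad3", nad4 = "nad4",
  nad4l = "nad4l", nad5 = "nad5", nad6 = "nad6",
  nd1 = "nad1", nd2 = "nad2", nd3 = "nad3", nd4 = "nad4",
  nd4l = "nad4l", nd5 = "nad5", nd6 = "nad6",
  rps3 = "rps3",
  rrnl = "rrnl", rnl = "rrnl", "rrn-l" = "rrnl", mtlsu = "rrnl",
  "rrn l" = "rrnl", "l-rrna" = "rrnl",
  rrns = "rrns", rns = "rrns", "rrn-s" = "rrns", mtssu = "rrns",
  "rrn s" = "rrns", "s-rrna" = "rrns"
)

#' The 15 mitochondrial core protein-coding genes
#'
#' Conserved across fungal mitogenomes: three ATP synthase subunits,
#' cytochrome b, three cytochrome oxidase subunits, seven NADH
#' dehydrogenase subunits and ribosomal protein S3.
#' @export
CORE_GENES <- c("atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
                "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6",
                "rps3")

#' Normalize a gene symbol
#'
#' Case-folds and maps through a synonym table (e.g. `"nad4L"` ->
#' `"nad4l"`, `"cytb"` -> `"cob"`). Unknown symbols are returned
#' lowercased unchanged.
#' @param name Gene symbol as annotated.
#' @export
normalize_gene_name <- function(name) {
  key <- tolower(trimws(name))
  out <- unname(GENE_SYNONYMS[key])
  ifelse(is.na(out), key, out)
}

new_gene_feature <- function(gene_name, start, end, strand, sequence,
                             n_intervals = 1L, kind = "gene") {
  stopifnot(end >= start, strand %in% c("+", "-"))
  structure(list(gene_name = gene_name, start = start, end = end,
                 strand = strand, sequence = sequence,
                 n_intervals = as.integer(n_intervals), kind = kind),
            class = "gene_feature")
}

new_mitogenome <- function(accession, organism, sequence, features,
                           is_circular = TRUE) {
  structure(list(accession = accession, organism = organism,
                 length_bp = nchar(sequence), sequence = sequence,
                 features = features, is_circular = is_circular),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s  %s  %d bp  %s  %d features\n",
              x$accession, x$organism, x$length_bp,
              if (x$is_circular) "circular" else "linear",
              length(x$features)))
  invisible(x)
}

# Parse a GenBank location string into an interval table plus strand.
# Handles 10..231, complement(...), join(a..b,c..d), single positions,
# and <, > partial markers (stripped).
parse_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("^complement\\(", loc)) {  # join(complement(...)) forms
    strand <- "-"
    loc <- gsub("complement\\(([^)]*)\\)", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  ints <- lapply(parts, function(p) {
    if (grepl("\\.\\.", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else {
      se <- rep(as.integer(p), 2L)
    }
    if (anyNA(se)) stop("parse error in location: ", loc, call. = FALSE)
    se
  })
  list(intervals = do.call(rbind, ints), strand = strand)
}

# Extract the strand-resolved sequence for a parsed location from the
# full genome sequence. Intervals with end > start wrap the origin on
# circular records (tail then head).
location_sequence <- function(genome_seq, intervals, strand, is_circular,
                              length_bp) {
  pieces <- apply(intervals, 1L, function(se) {
    s <- se[1]; e <- se[2]
    if (s >= 1L && e <= length_bp && s <= e) {
      substr(genome_seq, s, e)
    } else if (is_circular && s <= length_bp && e < s) {
      # origin-wrapping interval written as start..end with end < start
      paste0(substr(genome_seq, s, length_bp), substr(genome_seq, 1L, e))
    } else {
      stop("feature interval ", s, "..", e,
           " outside sequence bounds [1, ", length_bp, "]", call. = FALSE)
    }
  })
  seq <- paste(pieces, collapse = "")
  if (strand == "-") seq <- reverse_complement(seq)
  toupper(seq)
}

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses LOCUS, ACCESSION/VERSION, ORGANISM, the FEATURES table
#' (gene/CDS/rRNA/tRNA keys) and ORIGIN. Gene names are normalized via
#' [normalize_gene_name()]; feature sequences are strand-resolved
#' (reverse-complemented for `complement(...)` locations) and joined
#' features are concatenated in annotation order, with the interval
#' count retained (used downstream to flag intron-bearing genes).
#'
#' @param path Path to a GenBank flat file containing one record.
#' @return A `mitogenome` object.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L)
    stop("parse error: no LOCUS line in ", path, call. = FALSE)
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  length_bp <- suppressWarnings(as.integer(locus[which(locus == "bp") - 1L]))
  if (length(length_bp) == 0L || is.na(length_bp))
    stop("parse error at line ", locus_i[1],
         ": LOCUS line lacks a '<n> bp' length", call. = FALSE)
  is_circular <- any(grepl("circular", locus, ignore.case = TRUE))
  accession <- locus[2]
  vi <- grep("^VERSION", lines)
  if (length(vi) > 0L) {
    v <- strsplit(trimws(lines[vi[1]]), "\\s+")[[1]]
    if (length(v) >= 2L) accession <- v[2]
  }
  oi <- grep("^\\s{0,2}ORGANISM", lines)
  organism <- if (length(oi) > 0L)
    trimws(sub("^\\s*ORGANISM\\s*", "", lines[oi[1]])) else ""

  ori_i <- grep("^ORIGIN", lines)
  if (length(ori_i) == 0L)
    stop("parse error: no ORIGIN section in ", path, call. = FALSE)
  seq_lines <- lines[(ori_i[1] + 1L):length(lines)]
  end_i <- grep("^//", seq_lines)
  if (length(end_i) > 0L) seq_lines <- seq_lines[seq_len(end_i[1] - 1L)]
  genome_seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(genome_seq) != length_bp)
    stop("parse error: ORIGIN has ", nchar(genome_seq),
         " bases but LOCUS declares ", length_bp, call. = FALSE)

  feat_i <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat_i) > 0L) {
    block <- lines[(feat_i[1] + 1L):(ori_i[1] - 1L)]
    # a feature line has a key in columns 6-20; continuation lines are
    # further indented
    is_key <- grepl("^\\s{4,6}\\S", block)
    key_idx <- which(is_key)
    for (k in seq_along(key_idx)) {
      from <- key_idx[k]
      to <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(block)
      header <- strsplit(trimws(block[from]), "\\s+")[[1]]
      key <- header[1]
      if (!key %in% c("gene", "CDS", "rRNA", "tRNA")) next
      body <- block[from:to]
      # location may continue over lines until the first qualifier
      qual_start <- grep("^\\s+/", body)
      loc_end <- if (length(qual_start) > 0L) qual_start[1] - 1L else length(body)
      loc <- paste(trimws(sub("^\\s*\\S+\\s*", "", body[1])),
                   paste(trimws(body[seq_len(loc_end)[-1]]), collapse = ""),
                   sep = "")
      quals <- paste(trimws(body[seq_len(length(body)) > loc_end]),
                     collapse = " ")
      gene <- regmatches(quals, regexpr('/gene="[^"]*"', quals))
      label <- regmatches(quals, regexpr('/label="?[^"/ ]*"?', quals))
      product <- regmatches(quals, regexpr('/product="[^"]*"', quals))
      name <- if (length(gene) > 0L) {
        sub('/gene="([^"]*)"', "\\1", gene[1])
      } else if (length(label) > 0L) {
        gsub('"', "", sub("/label=", "", label[1]))
      } else if (length(product) > 0L) {
        sub('/product="([^"]*)"', "\\1", product[1])
      } else next
      pl <- parse_location(loc)
      seq <- location_sequence(genome_seq, pl$intervals, pl$strand,
                               is_circular, length_bp)
      features[[length(features) + 1L]] <- new_gene_feature(
        gene_name = normalize_gene_name(name),
        start = min(pl$intervals), end = max(pl$intervals),
        strand = pl$strand, sequence = seq,
        n_intervals = nrow(pl$intervals), kind = key)
    }
  }
  # prefer CDS/rRNA entries over bare gene entries for the same symbol
  kinds <- vapply(features, `[[`, "", "kind")
  names_ <- vapply(features, `[[`, "", "gene_name")
  drop <- kinds == "gene" & names_ %in% names_[kinds != "gene"]
  features <- features[!drop]
  new_mitogenome(accession, organism, genome_seq, features, is_circular)
}

#' Extract a named gene from a mitogenome
#'
#' Matching is on the normalized gene symbol. If a record carries several
#' copies (tRNAs commonly do), `copy` selects one by annotation order;
#' without it multiple matches raise an ambiguity error.
#'
#' @param record A `mitogenome`.
#' @param gene_name Gene symbol (any case/synonym).
#' @param copy Optional 1-based copy index among matching features.
#' @return A `gene_feature`.
#' @export
extract_gene <- function(record, gene_name, copy = NULL) {
  target <- normalize_gene_name(gene_name)
  names_ <- vapply(record$features, `[[`, "", "gene_name")
  hit <- which(names_ == target)
  if (length(hit) == 0L)
    stop("gene '", target, "' absent from ", record$accession,
         "; available: ", paste(sort(unique(names_)), collapse = ", "),
         call. = FALSE)
  if (length(hit) > 1L) {
    if (is.null(copy))
      stop("gene '", target, "' has ", length(hit), " copies in ",
           record$accession, "; give copy index", call. = FALSE)
    hit <- hit[copy]
  }
  record$features[[hit]]
}

#' Write sequences to FASTA
#'
#' @param entries Named character vector (names are record ids).
#' @param path Output path.
#' @export
write_fasta <- function(entries, path) {
  if (length(entries) > 0L) {
    ids <- names(entries)
    if (is.null(ids) || any(!nzchar(ids)))
      stop("every FASTA entry needs a nonempty id", call. = FALSE)
    if (anyDuplicated(ids))
      stop("duplicate FASTA ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           call. = FALSE)
    set <- Biostrings::BStringSet(entries)
    Biostrings::writeXStringSet(set, path)
  } else {
    file.create(path)
  }
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path Input path.
#' @return Named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(set)), names(set))
}

#' Per-record gene inventory
#'
#' @param records List of `mitogenome` objects.
#' @return data.frame with accession, gene, start, end, strand, length.
#' @export
gene_inventory <- function(records) {
  rows <- lapply(records, function(r) {
    if (length(r$features) == 0L) return(NULL)
    data.frame(
      accession = r$accession,
      gene = vapply(r$features, `[[`, "", "gene_name"),
      start = vapply(r$features, `[[`, 0L, "start"),
      end = vapply(r$features, `[[`, 0L, "end"),
      strand = vapply(r$features, `[[`, "", "strand"),
      length = vapply(r$features, function(f) nchar(f$sequence), 0L),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a mitogenome as a GenBank flat file
#'
#' Minimal but standards-shaped emission (LOCUS, VERSION, ORGANISM,
#' FEATURES with gene qualifiers, ORIGIN) so simulator output exercises
#' the same parser as deposited records.
#'
#' @param record A `mitogenome`.
#' @param path Output path.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (record$is_circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   UNA",
                     record$accession, record$length_bp, topo), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion, complete genome.",
                     record$organism), con)
  writeLines(sprintf("VERSION     %s", record$accession), con)
  writeLines("SOURCE      mitochondrion", con)
  writeLines(sprintf("  ORGANISM  %s", record$organism), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (f in record$features) {
    loc <- sprintf("%d..%d", f$start, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    key <- switch(f$kind, rRNA = "rRNA", tRNA = "tRNA", CDS = "CDS", "gene")
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$gene_name), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
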