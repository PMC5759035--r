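## Readers/writers for the plain-text formats the pipeline touches:
## FASTA/FASTQ (Phred+33) with self-describing "key=value" header tokens,
## TSV OTU tables (samples as rows), sample metadata and lineage TSVs.
## Parsing of the sequence container itself is delegated to Biostrings;
## this file owns the header-annotation dialect and validation.

TREATMENT_LEVELS <- c("inoculated", "uninoculated")
ORGAN_LEVELS <- c("root", "stem", "leaf", "stalk_bottom", "stalk_medium",
                  "stalk_upper")
COMPARTMENT_LEVELS <- c("exophytic", "endophytic", "rhizosphere")

#' Build an in-memory sequence record set
#'
#' Sequence sets are plain data frames with columns `id`, `sequence`, a
#' `quality` list column (integer Phred scores, or `NULL` entries for
#' FASTA-style records) and an `annotations` list column of named character
#' vectors parsed from whitespace-separated `key=value` header tokens.
#'
#' @param id character vector of record ids (unique, non-empty)
#' @param sequence DNA strings over A,C,G,T,N
#' @param quality optional list of integer Phred score vectors
#' @param annotations optional list of named character vectors
#' @return a `data.frame` of class `cbc_seqs`
#' @export
seq_records <- function(id, sequence, quality = NULL, annotations = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(id))) stop_cbc("sequence ids must be non-empty")
  if (anyDuplicated(id))
    stop_cbc("duplicated sequence id(s): %s",
             paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(sequence) != length(id))
    stop_cbc("id and sequence lengths differ")
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop_cbc("non-ACGTN characters in sequence(s): %s",
             paste(head(id[bad], 3), collapse = ", "))
  if (is.null(quality)) quality <- vector("list", length(id))
  if (is.null(annotations))
    annotations <- rep(list(character(0)), length(id))
  ok <- vapply(seq_along(id), function(i) {
    is.null(quality[[i]]) || length(quality[[i]]) == nchar(sequence[i])
  }, logical(1))
  if (!all(ok))
    stop_cbc("quality length != sequence length for: %s",
             paste(head(id[!ok], 3), collapse = ", "))
  df <- data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE)
  df$quality <- I(quality)
  df$annotations <- I(annotations)
  class(df) <- c("cbc_seqs", "data.frame")
  df
}

#' Fetch a header annotation across a record set
#'
#' @param records a `cbc_seqs` data frame
#' @param key annotation key, e.g. `"well"` or `"passes"`
#' @param default value used where the key is absent
#' @return character vector, one element per record
#' @export
seq_annot <- function(records, key, default = NA_character_) {
  vapply(records$annotations, function(a) {
    if (key %in% names(a)) a[[key]] else default
  }, character(1))
}

set_seq_annot <- function(records, key, values) {
  values <- as.character(values)
  records$annotations <- I(lapply(seq_len(nrow(records)), function(i) {
    a <- records$annotations[[i]]
    a[key] <- values[i]
    a
  }))
  records
}

parse_header_annotations <- function(headers) {
  lapply(strsplit(headers, "[ \t]+"), function(tok) {
    tok <- tok[-1]
    tok <- tok[grepl("=", tok, fixed = TRUE)]
    if (!length(tok)) return(character(0))
    kv <- regmatches(tok, regexpr("=", tok, fixed = TRUE), invert = TRUE)
    vals <- vapply(kv, `[`, character(1), 2)
    names(vals) <- vapply(kv, `[`, character(1), 1)
    vals
  })
}

format_header <- function(id, annotations) {
  extra <- vapply(annotations, function(a) {
    if (!length(a)) return("")
    paste0(" ", paste(names(a), unname(a), sep = "=", collapse = " "))
  }, character(1))
  paste0(id, extra)
}

#' Read sequences from FASTA or FASTQ
#'
#' FASTQ qualities must be Phred+33. Header tokens of the form
#' `key=value` after the id are parsed into the `annotations` column.
#'
#' @param path file path
#' @param format `"fasta"` or `"fastq"` (default: guessed from extension)
#' @return a `cbc_seqs` record set, input order preserved
#' @export
read_sequences <- function(path, format = NULL) {
  if (!file.exists(path)) stop_cbc("no such file: %s", path)
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format,
                                 with.qualities = (format == "fastq")),
    error = function(e) stop_cbc("parse error in %s: %s", path,
                                 conditionMessage(e)))
  headers <- names(set)
  ids <- sub("[ \t].*$", "", headers)
  if (anyDuplicated(ids))
    stop_cbc("duplicated id(s) in %s: %s", path,
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  quality <- vector("list", length(set))
  if (format == "fastq") {
    q <- S4Vectors::mcols(set)$qualities
    quality <- lapply(as.character(q), function(s) {
      as.integer(charToRaw(s)) - 33L
    })
  }
  seq_records(id = ids,
              sequence = as.character(set),
              quality = quality,
              annotations = parse_header_annotations(headers))
}

#' Write sequences to FASTA or FASTQ
#'
#' @param records a `cbc_seqs` record set
#' @param path output path
#' @param format `"fasta"` or `"fastq"`; FASTQ requires qualities on every
#'   record
#' @return `path`, invisibly
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  headers <- format_header(records$id, records$annotations)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    writeLines(paste0(">", headers, "\n", records$sequence), con)
  } else {
    missing_q <- vapply(records$quality, is.null, logical(1))
    if (any(missing_q))
      stop_cbc("FASTQ output needs qualities; missing for: %s",
               paste(head(records$id[missing_q], 3), collapse = ", "))
    qual <- vapply(records$quality, function(q) {
      rawToChar(as.raw(q + 33L))
    }, character(1))
    writeLines(paste0("@", headers, "\n", records$sequence, "\n+\n", qual),
               con)
  }
  invisible(path)
}

#' Read a samples x OTUs count table
#'
#' Plain TSV, first column `sample_id`, remaining columns OTU ids holding
#' non-negative integer counts.
#'
#' @param path TSV path
#' @return integer matrix with sample row names and OTU column names
#' @export
read_otu_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L || names(df)[1] != "sample_id")
    stop_cbc("OTU table must have 'sample_id' as first column: %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(df) && (any(is.na(m)) || any(m < 0) || any(m != round(m))))
    stop_cbc("OTU table counts must be non-negative integers: %s", path)
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample_id
  m
}

#' Write a samples x OTUs count table
#'
#' @param table integer matrix, rows samples, columns OTUs
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_otu_table <- function(table, path) {
  if (any(table < 0) || any(table != round(table)))
    stop_cbc("OTU table counts must be non-negative integers")
  df <- data.frame(sample_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `treatment`, `organ`, `compartment`; the
#' latter three are validated against their closed vocabularies.
#'
#' @param path TSV path
#' @return data frame with factor columns
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "treatment", "organ", "compartment")
  if (!all(need %in% names(df)))
    stop_cbc("metadata must contain columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_cbc("duplicated sample_id in %s", path)
  validate_metadata(df)
}

validate_metadata <- function(df) {
  chk <- function(col, levels) {
    bad <- setdiff(unique(df[[col]]), levels)
    if (length(bad))
      stop_cbc("invalid %s value(s): %s", col, paste(bad, collapse = ", "))
    factor(df[[col]], levels = levels)
  }
  df$treatment <- chk("treatment", TREATMENT_LEVELS)
  df$organ <- chk("organ", ORGAN_LEVELS)
  df$compartment <- chk("compartment", COMPARTMENT_LEVELS)
  df
}

#' Write sample metadata
#' @param metadata data frame as from [read_sample_metadata()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_sample_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

LINEAGE_RANKS <- c("phylum", "class", "order", "family", "genus")

#' Read a lineage TSV
#'
#' Two columns: id and a semicolon lineage string in the
#' `k__Bacteria;p__...;c__...;o__...;f__...;g__...` style. Empty rank
#' labels become `NA` (unknown).
#'
#' @param path TSV path
#' @return data frame with columns `id`, `phylum` ... `genus`
#' @export
read_lineage <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  parse_lineage_strings(df[[1]], df[[2]])
}

parse_lineage_strings <- function(ids, strings) {
  prefixes <- c(phylum = "p__", class = "c__", order = "o__",
                family = "f__", genus = "g__")
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  parts <- strsplit(strings, ";", fixed = TRUE)
  for (rank in LINEAGE_RANKS) {
    pre <- prefixes[[rank]]
    out[[rank]] <- vapply(parts, function(p) {
      hit <- p[startsWith(p, pre)]
      if (!length(hit)) return(NA_character_)
      lab <- sub(pre, "", hit[1], fixed = TRUE)
      if (nzchar(lab)) lab else NA_character_
    }, character(1))
  }
  out
}

format_lineage_strings <- function(lineage) {
  pre <- c("p__", "c__", "o__", "f__", "g__")
  vapply(seq_len(nrow(lineage)), function(i) {
    labs <- unlist(lineage[i, LINEAGE_RANKS])
    labs[is.na(labs)] <- ""
    paste0("k__Bacteria;", paste0(pre, labs, collapse = ";"))
  }, character(1))
}

#' Write a lineage TSV
#' @param lineage data frame with columns `id`, `phylum` ... `genus`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_lineage <- function(lineage, path) {
  df <- data.frame(id = lineage$id,
                   lineage = format_lineage_strings(lineage),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
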