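#' Read amplicon reads from a FASTA file
#'
#' Reads a (multi-)FASTA file into a sequence-record table, one record per
#' entry in file order, with bases uppercased and validated against the
#' `{A,C,G,T,N}` alphabet. Record ids are the first whitespace-delimited
#' token of each header; ids must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` of class `seq_records` with columns `id`, `bases`,
#'   `abundance` (all 1 on input) and a list column `members` holding the
#'   original read ids collapsed into each record.
#' @seealso [dereplicate()], [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  .validate_fasta_layout(path)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  bases <- toupper(as.character(set))
  new_seq_records(ids, bases)
}

# Light structural scan so parse errors can name the offending line:
# every header must be followed by at least one sequence line.
.validate_fasta_layout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("FASTA parse error: file is empty: ", path)
  is_hdr <- startsWith(lines, ">")
  hdr_at <- which(is_hdr)
  if (length(hdr_at) == 0) stop("FASTA parse error: no header lines in ", path)
  if (hdr_at[1] > 1 && any(nzchar(trimws(lines[seq_len(hdr_at[1] - 1)]))))
    stop("FASTA parse error at line 1: sequence data before first header")
  ends <- c(hdr_at[-1] - 1L, length(lines))
  for (k in seq_along(hdr_at)) {
    body <- lines[setdiff(seq(hdr_at[k], ends[k]), hdr_at[k])]
    if (sum(nchar(trimws(body))) == 0)
      stop("FASTA parse error at line ", hdr_at[k],
           ": header without sequence (", lines[hdr_at[k]], ")")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (length(a)) a else b

#' Construct a sequence-record table
#'
#' @param id Character vector of unique record ids.
#' @param bases Character vector of DNA strings over `{A,C,G,T,N}`
#'   (lowercase accepted and normalised).
#' @param abundance Positive integer read counts (default all 1).
#' @param members List of original read-id vectors, one per record; defaults
#'   to each record's own id. `abundance` must equal `lengths(members)`.
#' @return A `seq_records` data.frame.
#' @export
new_seq_records <- function(id, bases, abundance = NULL, members = NULL) {
  id <- as.character(id)
  bases <- toupper(as.character(bases))
  stopifnot(length(id) == length(bases))
  if (anyDuplicated(id))
    stop("duplicate record ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  bad <- which(!grepl("^[ACGTN]+$", bases))
  if (length(bad))
    stop("invalid characters (outside A/C/G/T/N) in record(s): ",
         paste(head(id[bad], 5), collapse = ", "))
  if (is.null(abundance)) abundance <- rep.int(1L, length(id))
  if (is.null(members)) members <- as.list(id)
  abundance <- as.integer(abundance)
  if (any(abundance < 1L)) stop("abundance must be >= 1")
  if (!identical(lengths(members), abundance) &&
      !all(lengths(members) == abundance))
    stop("abundance must equal length(members) for every record")
  out <- data.frame(id = id, bases = bases, abundance = abundance,
                    stringsAsFactors = FALSE)
  out$members <- members
  class(out) <- c("seq_records", "data.frame")
  out
}

# Coerce paths / character vectors / DNAStringSet to seq_records
.as_records <- function(x) {
  if (inherits(x, "seq_records")) return(x)
  if (is.character(x) && length(x) == 1 && !grepl("^[ACGTNacgtn]+$", x) &&
      file.exists(x))
    return(read_fasta(x))
  if (inherits(x, "XStringSet")) {
    nm <- names(x) %||% paste0("seq", seq_along(x))
    return(new_seq_records(nm, as.character(x)))
  }
  if (is.character(x)) {
    nm <- names(x) %||% paste0("seq", seq_along(x))
    return(new_seq_records(nm, unname(x)))
  }
  stop("cannot interpret input as sequence records")
}

#' Collapse identical reads and order records for clustering
#'
#' Exact full-length duplicates are collapsed into one record whose
#' abundance is the duplicate count and whose id is the first-seen read id.
#' Records are then sorted by abundance descending, with ties broken by the
#' sequence string (ascending, C locale) so that the resulting order -- and
#' hence the clustering stream -- is a pure function of the multiset of
#' input sequences, independent of input order.
#'
#' @param records A `seq_records` table (typically from [read_fasta()]).
#' @return A dereplicated, sorted `seq_records` table with attribute
#'   `n_reads` carrying the total input read count.
#' @export
dereplicate <- function(records) {
  records <- .as_records(records)
  n_reads <- sum(records$abundance)
  if (nrow(records) == 0) {
    attr(records, "n_reads") <- 0L
    return(records)
  }
  key <- records$bases
  first <- !duplicated(key)
  idx <- match(key, key[first])
  members <- split(unlist(records$members, use.names = FALSE),
                   rep(idx, records$abundance))
  # restore first-seen order of groups (split() orders by factor level)
  members <- members[as.character(seq_len(sum(first)))]
  out <- new_seq_records(
    id = records$id[first],
    bases = key[first],
    abundance = vapply(members, length, 1L),
    members = unname(members)
  )
  ord <- order(-out$abundance, out$bases, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("seq_records", "data.frame")
  attr(out, "n_reads") <- n_reads
  out
}

#' Write sequence records to FASTA
#'
#' @param records A `seq_records` table or named character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- .as_records(records)
  set <- Biostrings::BStringSet(records$bases)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write the OTU map and representative sequences of a clustering
#'
#' Writes a tab-separated file with one line per original read
#' (`read_id`, `otu_id`, `representative_id`, `is_core`) and a FASTA of OTU
#' representative sequences alongside.
#'
#' @param fit A fitted [dmsc()] object (or anything with compatible
#'   `assignments`, `representatives`, `core_flags` and `records` fields).
#' @param path Output TSV path.
#' @param fasta_path Representatives FASTA path; default replaces the TSV
#'   extension with `.rep.fasta`.
#' @return `path`, invisibly.
#' @export
write_otu_map <- function(fit, path, fasta_path = NULL) {
  if (is.null(fasta_path))
    fasta_path <- paste0(sub("\\.tsv$", "", path), ".rep.fasta")
  map <- otu_map(fit)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("read_id\totu_id\trepresentative_id\tis_core", con)
  if (nrow(map))
    writeLines(paste(map$read_id, map$otu_id, map$representative_id,
                     as.integer(map$is_core), sep = "\t"), con)
  reps <- fit$representatives
  if (length(reps)) {
    rec <- fit$records
    seqs <- rec$bases[match(reps, rec$id)]
    set <- Biostrings::BStringSet(seqs)
    names(set) <- paste0(names(reps), " representative=", reps)
    Biostrings::writeXStringSet(set, fasta_path)
  } else {
    cat("", file = fasta_path)
  }
  invisible(path)
}

#' Read an OTU map written by [write_otu_map()]
#'
#' @param path TSV path.
#' @return A data.frame with columns `read_id`, `otu_id`,
#'   `representative_id`, `is_core`.
#' @export
read_otu_map <- function(path) {
  out <- read.delim(path, colClasses = c("character", "character",
                                         "character", "integer"))
  out$is_core <- as.logical(out$is_core)
  out
}

#' Read-level OTU assignment table of a fit
#'
#' Expands a fitted clustering to one row per original input read.
#'
#' @param fit A fitted [dmsc()] object.
#' @return data.frame with columns `read_id`, `otu_id`,
#'   `representative_id`, `is_core`.
#' @export
otu_map <- function(fit) {
  rec <- fit$records
  if (is.null(rec) || nrow(rec) == 0)
    return(data.frame(read_id = character(), otu_id = character(),
                      representative_id = character(), is_core = logical(),
                      stringsAsFactors = FALSE))
  otus <- fit$assignments[rec$id]
  reps <- fit$representatives[otus]
  core <- fit$core_flags[rec$id]
  data.frame(
    read_id = unlist(rec$members, use.names = FALSE),
    otu_id = rep(unname(otus), rec$abundance),
    representative_id = rep(unname(reps), rec$abundance),
    is_core = rep(unname(core), rec$abundance),
    stringsAsFactors = FALSE
  )
}

#' Extract ground-truth taxon labels from read ids
#'
#' Intended for simulated data whose headers carry the generating taxon.
#' By default a `taxon=<label>` key is looked for first; failing that, the
#' token after the last `;` is used.
#'
#' @param ids Character vector of read ids / headers.
#' @param pattern Optional regular expression with one capture group
#'   extracting the label; overrides the default rules.
#' @return Named character vector of labels (names are `ids`); `NA` where no
#'   label was found.
#' @export
parse_taxon_labels <- function(ids, pattern = NULL) {
  lab <- rep(NA_character_, length(ids))
  if (!is.null(pattern)) {
    m <- regmatches(ids, regexec(pattern, ids))
    got <- lengths(m) >= 2
    lab[got] <- vapply(m[got], `[`, "", 2L)
  } else {
    m <- regmatches(ids, regexec("taxon=([^;|[:space:]]+)", ids))
    got <- lengths(m) >= 2
    lab[got] <- vapply(m[got], `[`, "", 2L)
    rest <- !got & grepl(";", ids)
    lab[rest] <- sub("^.*;", "", ids[rest])
  }
  names(lab) <- ids
  lab
}
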