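#' @keywords internal
"_PACKAGE"

#' The three experimental conditions, in trajectory order
#'
#' @return Character vector `c("pre_ischemia", "ischemia", "reperfusion")`.
#' @export
conditions <- function() c("pre_ischemia", "ischemia", "reperfusion")

QUANT_COLUMNS <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")

.parse_numeric <- function(x, column, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf("%s: non-numeric value '%s' in column '%s' at data row %d",
                 path, x[bad[1]], column, bad[1]), call. = FALSE)
  }
  out
}

#' Read a Salmon-style quantification table
#'
#' Parses one per-sample quantification file in the `quant.sf` dialect:
#' tab-separated with header columns `Name`, `Length`, `EffectiveLength`,
#' `TPM`, `NumReads`. Row order is preserved and identifiers are treated as
#' opaque case-sensitive strings.
#'
#' @param path Path to the tab-separated file.
#' @param sample_id Sample identifier attached to every record.
#' @return A data frame with columns `transcript_id`, `length`,
#'   `effective_length`, `tpm`, `num_reads`, `sample_id`.
#' @export
read_quant_table <- function(path, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  missing <- setdiff(QUANT_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    transcript_id = raw$Name,
    length = .parse_numeric(raw$Length, "Length", path),
    effective_length = .parse_numeric(raw$EffectiveLength, "EffectiveLength", path),
    tpm = .parse_numeric(raw$TPM, "TPM", path),
    num_reads = .parse_numeric(raw$NumReads, "NumReads", path),
    sample_id = if (nrow(raw) > 0) sample_id else character(0),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$transcript_id)) {
    dup <- out$transcript_id[duplicated(out$transcript_id)][1]
    stop(sprintf("%s: duplicate transcript identifier '%s'", path, dup),
         call. = FALSE)
  }
  if (nrow(out) > 0) {
    if (any(!is.finite(out$length)) || any(!is.finite(out$effective_length)) ||
        any(!is.finite(out$tpm)) || any(!is.finite(out$num_reads))) {
      stop(sprintf("%s: non-finite numeric value", path), call. = FALSE)
    }
    if (any(out$effective_length <= 0)) {
      stop(sprintf("%s: EffectiveLength must be > 0", path), call. = FALSE)
    }
    if (any(out$length <= 0)) {
      stop(sprintf("%s: Length must be > 0", path), call. = FALSE)
    }
    if (any(out$tpm < 0) || any(out$num_reads < 0)) {
      stop(sprintf("%s: TPM and NumReads must be non-negative", path),
           call. = FALSE)
    }
  }
  out
}

#' Read the sample design table
#'
#' TSV with columns `sample`, `patient`, `condition`. Conditions are
#' validated against [conditions()]; sample ids must be unique, every
#' condition must appear at least once, and each (patient, condition) pair
#' may occur at most once (one biopsy per state per patient).
#'
#' @param path Path to the design TSV.
#' @return A data frame with columns `sample_id`, `patient_id`, `condition`.
#' @export
read_design <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  missing <- setdiff(c("sample", "patient", "condition"), names(raw))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  design <- data.frame(sample_id = raw$sample, patient_id = raw$patient,
                       condition = raw$condition, stringsAsFactors = FALSE)
  validate_design(design)
  design
}

#' Validate a design table against the three-condition contract
#'
#' @param design Data frame with `sample_id`, `patient_id`, `condition`.
#' @return The design, invisibly, if valid; otherwise an error.
#' @export
validate_design <- function(design) {
  stopifnot(all(c("sample_id", "patient_id", "condition") %in% names(design)))
  bad <- setdiff(unique(design$condition), conditions())
  if (length(bad) > 0) {
    stop(sprintf("unknown condition '%s'; allowed values: %s",
                 bad[1], paste(conditions(), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  key <- paste(design$patient_id, design$condition, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (patient, condition) pair in design", call. = FALSE)
  }
  absent <- setdiff(conditions(), design$condition)
  if (length(absent) > 0) {
    stop(sprintf("condition '%s' has no samples", absent[1]), call. = FALSE)
  }
  invisible(design)
}

#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate
#' members within a set are deduplicated (first occurrence kept); a set with
#' no members is rejected.
#'
#' @param path Path to the GMT file.
#' @return A named list; each element is `list(set_name, description,
#'   members)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("%s: line %d has %d field(s); GMT requires name, description and at least one member",
                   path, i, length(fields)), call. = FALSE)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop(sprintf("%s: line %d: gene set '%s' has no members",
                   path, i, fields[1]), call. = FALSE)
    }
    sets[[i]] <- list(set_name = fields[1], description = fields[2],
                      members = members)
    nm[i] <- fields[1]
  }
  if (anyDuplicated(nm)) {
    stop(sprintf("%s: duplicate set name '%s'", path, nm[duplicated(nm)][1]),
         call. = FALSE)
  }
  names(sets) <- nm
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_name, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a transcript-to-gene map
#'
#' Two-column TSV (transcript, gene). A transcript mapped to more than one
#' gene is an error; an empty file yields an empty map with a warning.
#'
#' @param path Path to the TSV.
#' @param header Does the file carry a header line? Default `FALSE`.
#' @return Named character vector: `map[transcript_id] == gene_id`.
#' @export
read_tx2gene <- function(path, header = FALSE) {
  empty <- length(readLines(path, n = 1)) == 0
  raw <- if (empty) {
    data.frame(V1 = character(0), V2 = character(0))
  } else {
    utils::read.delim(path, header = header, sep = "\t",
                      colClasses = "character", check.names = FALSE)
  }
  if (nrow(raw) == 0) {
    warning(sprintf("%s: empty transcript-to-gene map", path), call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  if (ncol(raw) < 2) {
    stop(sprintf("%s: expected 2 columns (transcript, gene)", path),
         call. = FALSE)
  }
  tx <- raw[[1]]
  gene <- raw[[2]]
  conflict <- tapply(gene, tx, function(g) length(unique(g)))
  if (any(conflict > 1)) {
    stop(sprintf("%s: transcript '%s' maps to multiple genes",
                 path, names(conflict)[conflict > 1][1]), call. = FALSE)
  }
  keep <- !duplicated(tx)
  stats::setNames(gene[keep], tx[keep])
}

#' Assemble a count matrix from per-sample quantification tables
#'
#' Joins per-sample quant tables on `transcript_id`. Every sample must carry
#' the same transcript universe; a transcript present in one sample but not
#' another is an error rather than a silent intersection.
#'
#' @param quants List of data frames from [read_quant_table()].
#' @return A [count_matrix()] with per-sample effective lengths.
#' @export
quants_to_count_matrix <- function(quants) {
  stopifnot(length(quants) >= 1)
  ref <- quants[[1]]$transcript_id
  sample_ids <- vapply(quants, function(q) q$sample_id[1], character(1))
  for (q in quants) {
    if (length(q$transcript_id) != length(ref) || !all(q$transcript_id == ref)) {
      stop(sprintf("sample '%s' has a different transcript universe than sample '%s'",
                   q$sample_id[1], sample_ids[1]), call. = FALSE)
    }
  }
  counts <- vapply(quants, function(q) q$num_reads, numeric(length(ref)))
  efflen <- vapply(quants, function(q) q$effective_length, numeric(length(ref)))
  dimnames(counts) <- list(ref, sample_ids)
  dimnames(efflen) <- list(ref, sample_ids)
  count_matrix(counts, efflen)
}

#' Construct a validated count matrix
#'
#' The container used across the pipeline: a non-negative transcripts x
#' samples count matrix plus positive effective lengths (a per-transcript
#' vector, or a matrix when lengths vary by sample).
#'
#' @param counts Numeric matrix with transcript rownames and sample colnames.
#' @param effective_lengths Positive numeric vector (length `nrow(counts)`)
#'   or matrix with the same dimensions as `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, effective_lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have transcript rownames and sample colnames",
         call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (is.matrix(effective_lengths)) {
    if (!all(dim(effective_lengths) == dim(counts))) {
      stop("effective_lengths matrix must match counts dimensions",
           call. = FALSE)
    }
  } else {
    if (length(effective_lengths) != nrow(counts)) {
      stop("effective_lengths must have one value per transcript",
           call. = FALSE)
    }
  }
  if (any(!is.finite(effective_lengths)) || any(effective_lengths <= 0)) {
    stop("effective_lengths must be finite and > 0", call. = FALSE)
  }
  structure(list(counts = counts, effective_lengths = effective_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Write a data frame as a diff-stable TSV
#'
#' Single header line, tab separators, floats serialized with 6 significant
#' digits so repeated runs are byte-identical.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- as.character(signif(out[[j]], 6))
      out[[j]][is.na(df[[j]])] <- "NA"
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a TSV written by [write_tsv()]
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
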