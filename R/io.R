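# Readers and writers: FASTA sequences, the per-residue feature-table TSV
# dialect, model checkpoints and prediction/eval reports.
#
# Feature-table dialect (tab-separated, header mandatory, one row per
# residue): protein_id, pos (1-based, contiguous per protein), residue,
# pssm_1..pssm_20 (raw log-odds), rsa, ss_h, ss_e, ss_c, phi, psi, cs_re,
# cs_jsd, label. label is 0/1 or "." when unknown.

feature_table_columns <- function() {
  c("protein_id", "pos", "residue", paste0("pssm_", 1:20), "rsa",
    "ss_h", "ss_e", "ss_c", "phi", "psi", "cs_re", "cs_jsd", "label")
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named list of protein records `list(id, sequence)`; lowercase
#'   letters are uppercased. Duplicate identifiers or letters outside the
#'   20-residue-plus-dummy alphabet are rejected.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  if (file.size(path) == 0L) {
    warning("read_fasta: empty file: ", path)
    return(list())
  }
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("read_fasta: duplicate record id(s): ", paste(unique(dup), collapse = ", "))
  }
  chars <- toupper(as.character(seqs))
  legal <- names(aa_alphabet())
  records <- lapply(seq_along(ids), function(i) {
    letters_i <- strsplit(chars[[i]], "")[[1]]
    bad <- setdiff(unique(letters_i), legal)
    if (length(bad)) {
      stop("read_fasta: record ", i, " (", ids[i],
           ") contains illegal character(s): ", paste(bad, collapse = ", "))
    }
    list(id = ids[i], sequence = chars[[i]])
  })
  stats::setNames(records, ids)
}

#' Write sequences to a FASTA file
#'
#' @param proteins List of records with `id` and `sequence` (a
#'   `synthetic_corpus` is accepted directly).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  if (inherits(proteins, "synthetic_corpus")) proteins <- proteins$proteins
  seqs <- Biostrings::BStringSet(vapply(proteins, function(p) p$sequence, ""))
  names(seqs) <- vapply(proteins, function(p) p$id, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a per-residue feature table
#'
#' Numeric columns are serialized with 17 significant digits so that a
#' read-back reproduces every double bit-exactly.
#'
#' @param proteins List of protein records with `sequence`, `features` and
#'   optionally `labels` (a `synthetic_corpus` is accepted directly).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(proteins, path) {
  if (inherits(proteins, "synthetic_corpus")) proteins <- proteins$proteins
  tabs <- lapply(proteins, function(pr) {
    m <- nrow(pr$features)
    lab <- if (is.null(pr$labels)) rep(".", m) else as.character(pr$labels)
    cbind(data.frame(protein_id = pr$id, pos = seq_len(m),
                     residue = strsplit(pr$sequence, "")[[1]],
                     stringsAsFactors = FALSE),
          pr$features, data.frame(label = lab, stringsAsFactors = FALSE))
  })
  tab <- data.table::rbindlist(tabs)
  num_cols <- setdiff(feature_table_columns(), c("protein_id", "pos", "residue", "label"))
  for (cl in num_cols) {
    data.table::set(tab, j = cl, value = sprintf("%.17g", tab[[cl]]))
  }
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a per-residue feature table
#'
#' Validates the header, per-protein position contiguity and residue
#' letters; rows are ordered by `(protein_id, pos)`. A `"."` label marks a
#' residue without a known label (prediction-only mode).
#'
#' @param path TSV path in the dialect written by [write_feature_table()].
#' @param fasta Optional path to a FASTA file; residue columns are checked
#'   against its sequences.
#' @return Named list of protein records `list(id, sequence, labels,
#'   features)`; `labels` is `NULL` when absent.
#' @export
read_feature_table <- function(path, fasta = NULL) {
  tab <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("protein_id", "residue", "label")))
  missing_cols <- setdiff(feature_table_columns(), names(tab))
  if (length(missing_cols)) {
    stop("read_feature_table: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num_cols <- setdiff(feature_table_columns(),
                      c("protein_id", "pos", "residue", "label"))
  for (cl in num_cols) {
    data.table::set(tab, j = cl, value = as.numeric(tab[[cl]]))
  }
  data.table::setorder(tab, protein_id, pos)
  fasta_seqs <- if (!is.null(fasta)) read_fasta(fasta)
  split_tab <- split(as.data.frame(tab), tab$protein_id)
  records <- lapply(names(split_tab), function(id) {
    d <- split_tab[[id]]
    if (!identical(as.integer(d$pos), seq_len(nrow(d)))) {
      stop("read_feature_table: positions of ", id,
           " are not contiguous 1..L")
    }
    bad <- setdiff(unique(d$residue), names(aa_alphabet()))
    if (length(bad)) {
      stop("read_feature_table: illegal residue(s) in ", id, ": ",
           paste(bad, collapse = ", "))
    }
    sequence <- paste(d$residue, collapse = "")
    if (!is.null(fasta_seqs)) {
      if (is.null(fasta_seqs[[id]])) {
        stop("read_feature_table: ", id, " absent from FASTA")
      }
      if (fasta_seqs[[id]]$sequence != sequence) {
        stop("read_feature_table: residue column of ", id,
             " disagrees with FASTA sequence")
      }
    }
    labels <- if (all(d$label == ".")) NULL else {
      if (any(!d$label %in% c("0", "1"))) {
        stop("read_feature_table: labels of ", id, " must be 0, 1 or '.'")
      }
      as.integer(d$label)
    }
    feats <- d[, setdiff(feature_table_columns(),
                         c("protein_id", "pos", "residue", "label"))]
    rownames(feats) <- NULL
    list(id = id, sequence = sequence, labels = labels, features = feats)
  })
  stats::setNames(records, names(split_tab))
}

# --- checkpoints -------------------------------------------------------------

CHECKPOINT_VERSION <- 1L

#' Save a model checkpoint
#'
#' Stores the configuration, every weight tensor (bit-exact), the mode and
#' optional provenance/training summary.
#'
#' @param model A `bindsite_model` (or list with `config`, `weights`,
#'   `mode`).
#' @param path Output path (RDS).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  ck <- list(format_version = CHECKPOINT_VERSION,
             config = model$config,
             weights = model$weights,
             mode = model$mode %||% model$config$mode,
             std_provenance = model$std_provenance,
             history_summary = if (!is.null(model$history)) {
               list(iterations = nrow(model$history),
                    final_loss = utils::tail(model$history$loss, 1L))
             })
  saveRDS(ck, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a model checkpoint
#'
#' Rejects unknown format versions and weight sets inconsistent with the
#' stored configuration; corrupt files raise a clean error without partial
#' state.
#'
#' @param path Checkpoint path written by [save_checkpoint()].
#' @return A `bindsite_model` list with `config`, `weights`, `mode`.
#' @export
load_checkpoint <- function(path) {
  ck <- tryCatch(readRDS(path), error = function(e) {
    stop("load_checkpoint: cannot read ", path, ": ", conditionMessage(e))
  })
  if (!is.list(ck) || is.null(ck$format_version)) {
    stop("load_checkpoint: ", path, " is not a checkpoint")
  }
  if (ck$format_version != CHECKPOINT_VERSION) {
    stop("load_checkpoint: format version ", ck$format_version,
         " not supported (expected ", CHECKPOINT_VERSION, ")")
  }
  check_weight_shapes(ck$config, ck$weights)
  structure(list(config = ck$config, weights = ck$weights, mode = ck$mode,
                 std_provenance = ck$std_provenance,
                 history_summary = ck$history_summary),
            class = "bindsite_model")
}

#' Write predictions to TSV
#'
#' @param predictions Data frame from [predict_binding()].
#' @param path Output path; the decision threshold is recorded in a header
#'   comment line.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold=%s", attr(predictions, "threshold") %||% NA),
             con)
  utils::write.table(predictions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a JSON manifest for a synthetic corpus
#'
#' Records the generating configuration, seed and realized statistics.
#'
#' @param corpus A `synthetic_corpus`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_corpus_manifest <- function(corpus, path) {
  jsonlite::write_json(
    list(config = unclass(corpus$config),
         realized = corpus$realized,
         n_proteins = length(corpus$proteins)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
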