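# File formats: FASTA, substrate and annotation TSVs, site reports,
# fragment tables and model JSON persistence.
#
# All user-facing coordinates are 1-based inclusive, matching the P1
# convention of the window nomenclature.

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file (uncompressed or gzip).
#' @param permissive Accept non-canonical residue letters.
#' @return Named list of [annotated_sequence()]s (ids = headers up to the
#'   first whitespace; sequences upper-cased).
#' @export
read_fasta <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("FASTA parse error in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (!length(set)) stop("FASTA parse error: no records in '", path, "'",
                         call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  out <- Map(function(id, s) annotated_sequence(id, toupper(s),
                                                permissive = permissive),
             ids, as.character(set))
  names(out) <- ids
  out
}

#' Write sequences or fragments to FASTA
#'
#' Fragment tables get `parent|start-end` headers.
#'
#' @param x Named list of [annotated_sequence()]s or a `fragment_table`.
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "fragment_table")) {
    headers <- sprintf("%s|%d-%d", x$parent_id, x$start, x$end)
    seqs <- x$sequence
  } else {
    headers <- vapply(x, `[[`, character(1), "id")
    seqs <- vapply(x, `[[`, character(1), "residues")
  }
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  invisible(path)
}

#' Read a substrate training table
#'
#' TSV exchange format with columns `id`, `sequence`, `sites` (`sites` a
#' comma-joined list of 1-based P1 indices, possibly empty).
#'
#' @param path TSV file.
#' @return List of [substrate_record()]s.
#' @export
read_substrates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "sequence", "sites")
  if (!all(need %in% names(df))) {
    stop("substrate table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    sites <- if (nzchar(df$sites[i])) {
      as.integer(strsplit(df$sites[i], ",", fixed = TRUE)[[1]])
    } else integer(0)
    substrate_record(df$id[i], df$sequence[i], sites)
  })
}

#' Write a substrate training table
#'
#' @param substrates List of [substrate_record()]s.
#' @param path Output TSV.
#' @export
write_substrates <- function(substrates, path) {
  df <- data.frame(
    id = vapply(substrates, `[[`, character(1), "id"),
    sequence = vapply(substrates, `[[`, character(1), "residues"),
    sites = vapply(substrates, function(s) {
      paste(s$p1_sites, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-residue structural annotations
#'
#' TSV with columns `id`, `pos` (1-based), `residue`, `ss`, `rsa`, one row
#' per residue. Validated strictly against the sequences: every residue of
#' every annotated sequence must be covered, in order, with matching
#' residue letters.
#'
#' @param path TSV file.
#' @param seqs Named list of [annotated_sequence()]s to attach to.
#' @return The sequences with `ss`/`rsa` tracks attached.
#' @export
read_annotations <- function(path, seqs) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pos = "integer"))
  need <- c("id", "pos", "residue", "ss", "rsa")
  if (!all(need %in% names(df))) {
    stop("annotation table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (id in unique(df$id)) {
    if (!id %in% names(seqs)) {
      stop("annotation for unknown sequence '", id, "'", call. = FALSE)
    }
    rows <- df[df$id == id, , drop = FALSE]
    rows <- rows[order(rows$pos), , drop = FALSE]
    L <- nchar(seqs[[id]]$residues)
    if (!identical(rows$pos, seq_len(L))) {
      stop(sprintf("annotation mismatch for '%s': positions must cover 1..%d",
                   id, L), call. = FALSE)
    }
    expected <- chars(seqs[[id]]$residues)
    if (!identical(rows$residue, expected)) {
      bad <- which(rows$residue != expected)[1]
      stop(sprintf(
        "annotation mismatch for '%s' at position %d: residue '%s' != sequence '%s'",
        id, bad, rows$residue[bad], expected[bad]), call. = FALSE)
    }
    seqs[[id]] <- attach_structure(seqs[[id]],
                                   ss = paste(rows$ss, collapse = ""),
                                   rsa = paste(rows$rsa, collapse = ""))
  }
  seqs
}

#' Write per-residue structural annotations
#'
#' @param seqs Named list of annotated sequences (with ss/rsa tracks).
#' @param path Output TSV.
#' @export
write_annotations <- function(seqs, path) {
  rows <- lapply(seqs, function(s) {
    if (is.null(s$ss) || is.null(s$rsa)) return(NULL)
    L <- nchar(s$residues)
    data.frame(id = rep(s$id, L), pos = seq_len(L),
               residue = chars(s$residues), ss = chars(s$ss),
               rsa = chars(s$rsa), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, Filter(Negate(is.null), rows))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-site cleavage report
#'
#' One row per (sequence, protease, candidate site): columns
#' `sequence_id`, `protease`, `p1`, `window`, `score`, `confidence`,
#' `positive`, ordered deterministically by sequence, protease, then P1.
#'
#' @param sites data.frame with those columns (see [predict_sites()]).
#' @param path Output TSV; a `.json` mirror is written alongside when
#'   `json = TRUE`.
#' @param json Also write a JSON mirror.
#' @export
write_site_report <- function(sites, path, json = FALSE) {
  cols <- c("sequence_id", "protease", "p1", "window", "score",
            "confidence", "positive")
  stopifnot(all(cols %in% names(sites)))
  sites <- sites[order(sites$sequence_id, sites$protease, sites$p1),
                 cols, drop = FALSE]
  sites$score <- format_num(sites$score)
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (json) {
    jsonlite::write_json(sites, paste0(tools::file_path_sans_ext(path),
                                       ".json"),
                         dataframe = "rows", na = "null", digits = NA)
  }
  invisible(path)
}

#' Write a fragment table
#'
#' Columns `parent_id`, `start`, `end`, `length`, `sequence`, `score`,
#' `mw`, `pi`, `steps` (producing events as `protease:p1` joined by `;`).
#'
#' @param fragments An annotated `fragment_table` (see
#'   [annotate_fragments()]).
#' @param path Output TSV.
#' @param fasta Optional FASTA mirror path.
#' @export
write_fragment_table <- function(fragments, path, fasta = NULL) {
  df <- fragments
  df$steps <- vapply(fragments$steps, function(s) {
    if (is.null(s)) "" else paste(sprintf("%s:%d", s$protease, s$p1),
                                  collapse = ";")
  }, character(1))
  if (is.null(df$mw)) df$mw <- NA_real_
  if (is.null(df$pi)) df$pi <- NA_real_
  for (col in c("score", "mw", "pi")) df[[col]] <- format_num(df[[col]])
  df <- df[, c("parent_id", "start", "end", "length", "sequence", "score",
               "mw", "pi", "steps"), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) write_fasta(fragments, fasta)
  invisible(path)
}

# fixed-precision numeric formatting so outputs are byte-stable
format_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

#' Write an evaluation metrics report
#'
#' @param metrics Named list of [classification_metrics()] (name =
#'   protease or dataset label).
#' @param path Output TSV; `json = TRUE` adds a JSON mirror.
#' @param json Also write a JSON mirror.
#' @export
write_metrics <- function(metrics, path, json = FALSE) {
  df <- do.call(rbind, lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    data.frame(label = nm, tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
               precision = format_num(m$precision),
               sensitivity = format_num(m$sensitivity),
               specificity = format_num(m$specificity),
               f1 = format_num(m$f1), stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (json) {
    jsonlite::write_json(
      lapply(metrics, unclass),
      paste0(tools::file_path_sans_ext(path), ".json"),
      auto_unbox = TRUE, na = "string", digits = NA)
  }
  invisible(path)
}

#' Save a scoring model as JSON
#'
#' One JSON document per protease holding all matrices (row = character,
#' eight columns P4..P4'), background vectors, weights, threshold, feature
#' set and training metadata. [load_model()] restores a model that scores
#' every window identically; save -> load -> save is byte-stable.
#'
#' @param model A [scoring_model()].
#' @param path Output `.json` file.
#' @export
save_model <- function(model, path) {
  doc <- list(
    format = "lysocleave-model",
    format_version = 1L,
    protease = model$protease,
    feature_set = model$feature_set,
    weighted = model$weighted,
    threshold = model$threshold,
    features = lapply(model$pssms, function(p) {
      list(alphabet = rownames(p$raw),
           raw = apply(p$raw, 1, as.numeric, simplify = FALSE),
           scaled = apply(p$scaled, 1, as.numeric, simplify = FALSE),
           n_windows = p$n_windows)
    }),
    background = lapply(model$background, function(b) {
      as.list(stats::setNames(as.numeric(b), names(b)))
    }),
    weights = if (model$weighted) as.list(model$weights),
    metadata = model$metadata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a scoring model from JSON
#'
#' @param path A [save_model()] file.
#' @return The restored [scoring_model()].
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  if (!identical(doc$format, "lysocleave-model")) {
    stop("not a lysocleave model file: ", path, call. = FALSE)
  }
  pssms <- lapply(names(doc$features), function(f) {
    fd <- doc$features[[f]]
    to_mat <- function(rows) {
      m <- do.call(rbind, rows)
      dimnames(m) <- list(fd$alphabet, WINDOW_POSITIONS)
      m
    }
    structure(list(feature = f, raw = to_mat(fd$raw),
                   scaled = to_mat(fd$scaled), n_windows = fd$n_windows),
              class = "feature_pssm")
  })
  names(pssms) <- names(doc$features)
  background <- lapply(names(doc$background), function(f) {
    b <- unlist(doc$background[[f]])
    structure(as.numeric(b), names = names(b), feature = f,
              class = "background_freq")
  })
  names(background) <- names(doc$background)
  weights <- if (isTRUE(doc$weighted)) unlist(doc$weights)
  scoring_model(doc$protease, pssms, background, doc$threshold,
                weights = weights, feature_set = doc$feature_set,
                metadata = doc$metadata)
}
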