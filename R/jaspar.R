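# JASPAR-format PFM text I/O and PFM-to-PFM similarity.

#' Read a JASPAR-format PFM database
#'
#' Parses the standard JASPAR text layout: a `>ID NAME` header followed by
#' four rows `A [ counts ]` ... `T [ counts ]` (brackets optional). A
#' `collection=LABEL` token in the header (e.g. `CORE`, `POLII`) is read as
#' a reporting label, defaulting to `"CORE"`.
#'
#' @param path Path to the database file.
#' @return A list of records: `id`, `name`, `collection`, `pfm` (4 x width
#'   matrix, rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  assert_that(length(heads) > 0, "no JASPAR records found")
  purrr::map(seq_along(heads), function(i) {
    h <- lines[heads[i]]
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    body <- lines[(heads[i] + 1):to]
    toks <- strsplit(sub("^>\\s*", "", h), "\\s+")[[1]]
    coll <- sub("^collection=", "", grep("^collection=", toks, value = TRUE))
    rows <- lapply(body[1:4], function(l) {
      stripped <- sub("^\\s*[ACGT]", "", l)
      as.numeric(regmatches(stripped, gregexpr("[0-9.]+", stripped))[[1]])
    })
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- DNA
    list(id = toks[1], name = if (length(toks) >= 2) toks[2] else toks[1],
         collection = if (length(coll)) coll else "CORE", pfm = pfm)
  })
}

#' Write PFMs in JASPAR text format
#'
#' @param pfms List of records as returned by [read_jaspar()], or a named
#'   list of 4 x width matrices.
#' @param path Output path.
#' @export
write_jaspar <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(pfms)) {
    rec <- pfms[[i]]
    if (is.matrix(rec)) {
      rec <- list(id = names(pfms)[i] %||% sprintf("motif_%d", i),
                  name = names(pfms)[i] %||% sprintf("motif_%d", i),
                  collection = "CORE", pfm = rec)
    }
    writeLines(sprintf(">%s %s collection=%s", rec$id, rec$name,
                       rec$collection %||% "CORE"), con)
    for (b in DNA) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(rec$pfm[b, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

# per-column similarity of two frequency columns: 2 - sum |q - t|
pfm_col_score <- function(q, t) 2 - sum(abs(q - t))

#' PFM similarity against a motif database
#'
#' For every database motif, the shorter matrix slides ungapped along the
#' longer; at each offset the column-normalised frequency vectors score
#' `2 - sum |q_b - t_b|` per column, and
#' `relScore = 100 * total / (2 * aligned width)` with aligned width the
#' shorter motif's width. The best offset per database motif is kept and
#' matches above `rel_score_min` are returned sorted descending.
#'
#' @param query A 4 x width count or frequency matrix (rows A, C, G, T).
#' @param database List of records from [read_jaspar()].
#' @param rel_score_min Reporting threshold in percent (default 90).
#' @return Tibble of class `asqtl_pfm_match`: database_id, database_name,
#'   collection, rel_score, offset.
#' @export
pfm_similarity <- function(query, database, rel_score_min = 90) {
  qf <- sweep(query, 2, pmax(colSums(query), .Machine$double.eps), "/")
  res <- purrr::map_dfr(database, function(rec) {
    tf <- sweep(rec$pfm, 2, pmax(colSums(rec$pfm), .Machine$double.eps), "/")
    wq <- ncol(qf); wt <- ncol(tf)
    short <- if (wq <= wt) qf else tf
    long <- if (wq <= wt) tf else qf
    ws <- ncol(short); wl <- ncol(long)
    best <- -Inf; best_off <- 0L
    for (off in 0:(wl - ws)) {
      sc <- sum(vapply(seq_len(ws), function(j) {
        pfm_col_score(short[, j], long[, j + off])
      }, 0))
      if (sc > best) { best <- sc; best_off <- off }
    }
    tibble(database_id = rec$id, database_name = rec$name,
           collection = rec$collection,
           rel_score = 100 * best / (2 * ws), offset = best_off)
  })
  if (nrow(res) == 0) {
    res <- tibble(database_id = character(), database_name = character(),
                  collection = character(), rel_score = numeric(),
                  offset = integer())
  }
  out <- res |> filter(.data$rel_score > rel_score_min) |>
    arrange(dplyr::desc(.data$rel_score))
  class(out) <- c("asqtl_pfm_match", class(out))
  out
}
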