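#' Read a document collection from disk
#'
#' Documents are plain-text files accompanied by a delimited metadata
#' table (TSV) with columns `doc_id`, optional `file` (defaults to
#' `<doc_id>.txt`), optional `patient_id` and optional `dct` (ISO date).
#' Text is read byte-exactly -- no whitespace normalization -- so standoff
#' offsets stay valid. A missing DCT yields a document with an absent
#' anchor plus a warning; a metadata row pointing at a missing file is an
#' error naming the row.
#'
#' @param dir directory containing the text files
#' @param metadata path to the metadata TSV, or a data frame
#' @return a list of [document()]s
#' @export
read_documents <- function(dir, metadata) {
  md <- if (is.data.frame(metadata)) metadata else
    utils::read.delim(metadata, stringsAsFactors = FALSE,
                      colClasses = "character")
  if (!"doc_id" %in% names(md))
    stop("read_documents: metadata lacks a doc_id column")
  lapply(seq_len(nrow(md)), function(i) {
    row <- md[i, ]
    fn <- if (!is.null(row$file) && !is.na(row$file) && nzchar(row$file))
      row$file else paste0(row$doc_id, ".txt")
    path <- file.path(dir, fn)
    if (!file.exists(path))
      stop("read_documents: row ", i, " (", row$doc_id,
           "): file not found: ", path)
    text <- readChar(path, file.info(path)$size, useBytes = FALSE)
    dct <- NULL
    if (!is.null(row$dct) && !is.na(row$dct) && nzchar(row$dct)) {
      dct <- tryCatch(as.Date(row$dct), error = function(e) NA)
      if (is.na(dct))
        stop("read_documents: row ", i, " (", row$doc_id,
             "): malformed dct \"", row$dct, "\"")
    } else {
      warning("read_documents: ", row$doc_id, " has no DCT; relative ",
              "expressions will normalize to placeholders", call. = FALSE)
    }
    meta <- list()
    if (!is.null(row$patient_id) && !is.na(row$patient_id))
      meta$patient_id <- row$patient_id
    document(row$doc_id, text, dct = dct, meta = meta)
  })
}

#' Write a document collection to disk
#'
#' Inverse of [read_documents()]: one `<doc_id>.txt` per document plus a
#' `metadata.tsv`. Byte-deterministic given identical inputs.
#'
#' @param docs list of [document()]s
#' @param dir output directory (created if needed)
#' @return the metadata path, invisibly
#' @export
write_documents <- function(docs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- data.frame(
    doc_id = vapply(docs, `[[`, character(1), "doc_id"),
    file = paste0(vapply(docs, `[[`, character(1), "doc_id"), ".txt"),
    patient_id = vapply(docs, function(d)
      as.character(d$meta$patient_id %||% ""), character(1)),
    dct = vapply(docs, function(d)
      if (is.null(d$dct)) "" else format(d$dct), character(1)),
    stringsAsFactors = FALSE)
  for (d in docs) {
    con <- file(file.path(dir, paste0(d$doc_id, ".txt")), "wb")
    writeChar(d$text, con, eos = NULL)
    close(con)
  }
  path <- file.path(dir, "metadata.tsv")
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write annotations in the standoff dialect
#'
#' Brat-style tab-separated standoff: one span line
#' `T<i> <TAB> <TYPE> <start> <end> <TAB> <surface>` per expression
#' (offsets 0-based, half-open), plus one value line
#' `A<i> <TAB> value T<i> <value>` for each normalized expression.
#' Surfaces containing tabs or newlines are rejected.
#'
#' @param ann a `psytimex_annotations` object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_standoff <- function(ann, path) {
  stopifnot(inherits(ann, "psytimex_annotations"))
  lines <- character(0)
  for (i in seq_along(ann$expressions)) {
    e <- ann$expressions[[i]]
    if (grepl("[\t\n]", e$surface))
      stop("write_standoff: surface of T", i, " contains tab/newline")
    lines <- c(lines, sprintf("T%d\t%s %d %d\t%s", i, e$type, e$start,
                              e$end, e$surface))
    if (!is.null(e$value))
      lines <- c(lines, sprintf("A%d\tvalue T%d %s", i, i,
                                serialize_value(e$value)))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read annotations from the standoff dialect
#'
#' Inverse of [write_standoff()]. Offsets are validated against the
#' document; an out-of-range span or a surface that does not match the
#' document text is an error naming the record. Value strings are parsed
#' under the canonical grammar (with the span's type as disambiguation
#' hint). Record order in the file is irrelevant; the result is sorted.
#'
#' @param path standoff file
#' @param doc the [document()] the annotations refer to
#' @export
read_standoff <- function(path, doc) {
  stopifnot(inherits(doc, "psytimex_document"))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  spans <- list(); values <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    id <- parts[1]
    if (startsWith(id, "T")) {
      if (length(parts) != 3) stop("read_standoff: malformed span line: ", ln)
      hdr <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      if (length(hdr) != 3) stop("read_standoff: malformed span header: ", ln)
      spans[[id]] <- list(type = hdr[1], start = as.integer(hdr[2]),
                          end = as.integer(hdr[3]), surface = parts[3])
    } else if (startsWith(id, "A")) {
      if (length(parts) != 2) stop("read_standoff: malformed value line: ", ln)
      m <- regmatches(parts[2], regexec("^value (T[0-9]+) (.+)$", parts[2]))[[1]]
      if (length(m) != 3) stop("read_standoff: malformed value line: ", ln)
      values[[m[2]]] <- m[3]
    } else {
      stop("read_standoff: unknown record id: ", id)
    }
  }
  n <- nchar(doc$text)
  exprs <- lapply(names(spans), function(id) {
    sp <- spans[[id]]
    if (sp$start < 0 || sp$end > n)
      stop("read_standoff: record ", id, ": span [", sp$start, ",", sp$end,
           ") outside document of length ", n)
    got <- substr(doc$text, sp$start + 1, sp$end)
    if (!identical(got, sp$surface))
      stop("read_standoff: record ", id, ": surface mismatch (\"",
           sp$surface, "\" vs \"", got, "\")")
    val <- if (!is.null(values[[id]]))
      parse_value(values[[id]], type = sp$type) else NULL
    time_expression(sp$start, sp$end, sp$surface, sp$type, value = val)
  })
  annotation_set(doc$doc_id, exprs, doc = doc)
}

TIMEX3_TYPE_MAP <- c(DATE = "DATE", TIME = "TIME", DURATION = "DURATION",
                     FREQUENCY = "FREQUENCY", SET = "FREQUENCY")

#' Read an i2b2-2012-style TIMEX3 XML file
#'
#' Expects a `<TEXT>` element with the narrative and `<TIMEX3>` tags
#' carrying `type`, `val` and (1-based, end-inclusive) `start`/`end`
#' offsets plus the surface `text`. TIMEX3 types map onto the package's
#' labels (`SET` folds into `FREQUENCY`); unknown types are kept, typed
#' `DATE`, with the original label in `meta$orig_type` and a warning.
#' Values are parsed leniently: strings outside the canonical grammar are
#' preserved verbatim as [raw_value()]s -- this adapter never converts
#' foreign values into the SIN/UNT/age scheme.
#'
#' @param path an XML file
#' @return `list(doc = <document>, ann = <annotations>)`
#' @export
read_timex3_xml <- function(path) {
  x <- xml2::read_xml(path)
  text_node <- xml2::xml_find_first(x, ".//TEXT")
  if (is.na(text_node)) stop("read_timex3_xml: no TEXT element")
  text <- xml2::xml_text(text_node)
  doc <- document(tools::file_path_sans_ext(basename(path)), text)
  nodes <- xml2::xml_find_all(x, ".//TIMEX3")
  n <- nchar(text)
  exprs <- list()
  for (nd in nodes) {
    ty_raw <- toupper(xml2::xml_attr(nd, "type"))
    ty <- TIMEX3_TYPE_MAP[ty_raw]
    meta <- list()
    if (is.na(ty)) {
      warning("read_timex3_xml: unknown TIMEX3 type \"", ty_raw,
              "\"; kept as DATE with meta$orig_type", call. = FALSE)
      ty <- "DATE"
      meta$orig_type <- ty_raw
    }
    surf <- xml2::xml_attr(nd, "text")
    s <- suppressWarnings(as.integer(xml2::xml_attr(nd, "start")))
    e <- suppressWarnings(as.integer(xml2::xml_attr(nd, "end")))
    if (!is.na(s) && !is.na(e)) {
      s0 <- s - 1L; e0 <- e            # 1-based inclusive -> 0-based half-open
      if (!is.na(surf) && !identical(substr(text, s0 + 1, e0), surf)) {
        # tolerate half-open source offsets
        if (identical(substr(text, s + 1, e), surf)) { s0 <- s; e0 <- e }
        else stop("read_timex3_xml: offsets of \"", surf,
                  "\" do not match the text")
      }
      if (is.na(surf)) surf <- substr(text, s0 + 1, e0)
    } else {
      if (is.na(surf)) stop("read_timex3_xml: TIMEX3 without offsets or text")
      hit <- regexpr(surf, text, fixed = TRUE)
      if (hit == -1) stop("read_timex3_xml: surface \"", surf,
                          "\" not found in text")
      s0 <- as.integer(hit) - 1L
      e0 <- s0 + attr(hit, "match.length")
    }
    if (s0 < 0 || e0 > n) stop("read_timex3_xml: span outside text")
    val_str <- xml2::xml_attr(nd, "val")
    val <- if (is.na(val_str) || !nzchar(val_str)) NULL else
      tryCatch(parse_value(val_str, type = unname(ty)),
               error = function(err) raw_value(val_str))
    exprs[[length(exprs) + 1L]] <-
      time_expression(s0, e0, surf, unname(ty), value = val, meta = meta)
  }
  list(doc = doc, ann = annotation_set(doc$doc_id, exprs, doc = doc))
}
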