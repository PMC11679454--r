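# Turtle 1.1 serialization for triple-graph tibbles, and a parser for the
# (prefixed-name / IRI / typed-literal) subset the serializer emits.  No RDF
# toolkit ships with this R stack, so the format support lives here; the
# parser reports the file line of the first offending token.

turtle_prefixes <- function(vocab) {
  c(foo = vocab$foo_ns, geo = vocab$wgs84_ns, ext = vocab$ext_ns,
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#", xsd = XSD_NS)
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "", fixed = TRUE)[[1]]
    res <- character(0); j <- 1L
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        res <- c(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        res <- c(res, chars[j]); j <- j + 1L
      }
    }
    out[i] <- paste0(res, collapse = "")
  }
  out
}

compact_iri <- function(iri, prefixes) {
  for (p in names(prefixes)) {
    ns <- prefixes[[p]]
    hit <- startsWith(iri, ns)
    local <- substring(iri, nchar(ns) + 1L)
    ok <- hit & grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local)
    iri[ok] <- paste0(p, ":", local[ok])
  }
  ifelse(grepl("^[A-Za-z_][A-Za-z0-9_-]*:[A-Za-z_][A-Za-z0-9_-]*$", iri),
         iri, paste0("<", iri, ">"))
}

format_term <- function(object, object_type, datatype, prefixes) {
  ifelse(object_type == "iri",
         compact_iri(object, prefixes),
         paste0("\"", escape_literal(object), "\"",
                ifelse(is.na(datatype), "",
                       paste0("^^", compact_iri(datatype, prefixes)))))
}

#' Serialize a triple graph to Turtle
#'
#' W3C Turtle 1.1 with prefix declarations for the FOO, WGS84 geo, RDF, XSD
#' and extension namespaces; triples grouped by subject with `;`
#' separators and `a` for `rdf:type`.  [parse_turtle()] returns an equal
#' set of triples.
#'
#' @param graph a triple-graph tibble.
#' @param path output file path.
#' @param vocab a [foo_vocabulary()] (supplies the prefix table).
#' @return `path`, invisibly.
#' @export
serialize_turtle <- function(graph, path, vocab = foo_vocabulary()) {
  prefixes <- turtle_prefixes(vocab)
  header <- paste0("@prefix ", names(prefixes), ": <", unname(prefixes), "> .")
  lines <- header
  g <- dplyr::arrange(tibble::as_tibble(graph), .data$subject, .data$predicate,
                      .data$object)
  if (nrow(g) > 0) {
    g$subj_txt <- compact_iri(g$subject, prefixes)
    g$pred_txt <- ifelse(g$predicate == RDF_TYPE, "a",
                         compact_iri(g$predicate, prefixes))
    g$obj_txt <- format_term(g$object, g$object_type, g$datatype, prefixes)
    blocks <- split(g, factor(g$subject, levels = unique(g$subject)))
    body <- vapply(blocks, function(b) {
      po <- paste0(b$pred_txt, " ", b$obj_txt)
      paste0(b$subj_txt[1], " ",
             paste(po, collapse = " ;\n    "), " .")
    }, character(1))
    lines <- c(lines, "", unname(body))
  }
  writeLines(lines, path)
  invisible(path)
}

TOKEN_REGEX <- paste0(
  "(@prefix)",
  "|(<[^<>\"{}|^`\\\\[:space:]]*>)",
  "|(\"(?:[^\"\\\\]|\\\\.)*\")",
  "|(\\^\\^)",
  "|([;,.])",
  "|([A-Za-z_][A-Za-z0-9_-]*)?:([A-Za-z_][A-Za-z0-9_.-]*)?",
  "|\\ba\\b",
  "|(#[^\n]*)"
)

tokenize_turtle <- function(txt) {
  m <- gregexpr(TOKEN_REGEX, txt, perl = TRUE)[[1]]
  if (m[1] == -1) m <- integer(0)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tokens <- substring(txt, starts, starts + lens - 1L)
  # every character outside tokens must be whitespace
  covered <- rep(FALSE, nchar(txt))
  for (i in seq_along(starts)) {
    covered[seq.int(starts[i], length.out = lens[i])] <- TRUE
  }
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  bad <- which(!covered & !grepl("^[[:space:]]$", chars))
  newlines <- which(chars == "\n")
  line_of <- function(pos) findInterval(pos - 0.5, newlines) + 1L
  if (length(bad) > 0) {
    stop("Turtle parse error at line ", line_of(bad[1]),
         ": unexpected character '", chars[bad[1]], "'", call. = FALSE)
  }
  keep <- !startsWith(tokens, "#")
  list(tokens = tokens[keep], lines = line_of(starts[keep]))
}

#' Parse a Turtle file into a triple graph
#'
#' Parses the Turtle subset emitted by [serialize_turtle()] (prefix
#' declarations, IRIs, prefixed names, `a`, typed and plain string
#' literals, `;`/`,` continuation).  Malformed input raises an error
#' naming the offending line.
#'
#' @param path Turtle file path.
#' @return a triple-graph tibble.
#' @export
parse_turtle <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  tk <- tokenize_turtle(txt)
  tokens <- tk$tokens; lines <- tk$lines
  prefixes <- character(0)
  i <- 1L
  n <- length(tokens)
  fail <- function(msg, at = i) {
    line <- if (at <= n) lines[at] else if (n > 0) lines[n] else 1L
    stop("Turtle parse error at line ", line, ": ", msg, call. = FALSE)
  }
  expand <- function(tok, at) {
    if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
    if (grepl("^([A-Za-z_][A-Za-z0-9_-]*)?:", tok)) {
      parts <- regmatches(tok, regexec("^([A-Za-z0-9_-]*):(.*)$", tok))[[1]]
      pfx <- parts[2]
      if (!pfx %in% names(prefixes)) fail(paste0("unknown prefix '", pfx, ":'"), at)
      return(paste0(prefixes[[pfx]], parts[3]))
    }
    fail(paste0("expected IRI or prefixed name, got '", tok, "'"), at)
  }
  acc <- vector("list", 512L); n_acc <- 0L
  push <- function(s, p, o, ot, dt) {
    n_acc <<- n_acc + 1L
    if (n_acc > length(acc)) length(acc) <<- 2L * length(acc)
    acc[[n_acc]] <<- c(s, p, o, ot, dt)
  }
  while (i <= n) {
    if (tokens[i] == "@prefix") {
      if (i + 3L > n || !grepl("^([A-Za-z_][A-Za-z0-9_-]*)?:$", tokens[i + 1L]) ||
          !startsWith(tokens[i + 2L], "<") || tokens[i + 3L] != ".") {
        fail("malformed @prefix directive")
      }
      pfx <- sub(":$", "", tokens[i + 1L])
      prefixes[pfx] <- substr(tokens[i + 2L], 2L, nchar(tokens[i + 2L]) - 1L)
      i <- i + 4L
      next
    }
    subj <- expand(tokens[i], i); i <- i + 1L
    repeat {
      if (i > n) fail("unexpected end of input: predicate expected")
      pred <- if (tokens[i] == "a") RDF_TYPE else expand(tokens[i], i)
      i <- i + 1L
      repeat {
        if (i > n) fail("unexpected end of input: object expected")
        tok <- tokens[i]
        if (startsWith(tok, "\"")) {
          obj <- unescape_literal(substr(tok, 2L, nchar(tok) - 1L))
          otype <- "literal"; dtype <- NA_character_
          i <- i + 1L
          if (i <= n && tokens[i] == "^^") {
            if (i + 1L > n) fail("datatype IRI expected after '^^'")
            dtype <- expand(tokens[i + 1L], i + 1L)
            i <- i + 2L
          }
        } else {
          obj <- expand(tok, i); otype <- "iri"; dtype <- NA_character_
          i <- i + 1L
        }
        push(subj, pred, obj, otype, dtype)
        if (i <= n && tokens[i] == ",") { i <- i + 1L; next }
        break
      }
      if (i > n) fail("unexpected end of input: '.' expected")
      if (tokens[i] == ";") { i <- i + 1L; next }
      if (tokens[i] == ".") { i <- i + 1L; break }
      fail(paste0("expected ';' or '.', got '", tokens[i], "'"))
    }
  }
  if (n_acc == 0L) return(triple_graph())
  mat <- do.call(rbind, acc[seq_len(n_acc)])
  as_triple_graph(tg_rows(mat[, 1], mat[, 2], mat[, 3], mat[, 4], mat[, 5]))
}
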