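## RDF serialization. The package writes canonicalized N-Triples (sorted,
## diffable), a one-statement-per-line Turtle dialect with standard
## prefixes, and RDF/XML; it reads back all three plus TriG (named-graph
## blocks collapsed into the default graph). Readers cover the subset the
## writers emit and report malformed input with its line number.

nt_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

nt_unescape <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

nt_term_o <- function(o, o_type, o_datatype) {
  ifelse(o_type == "iri", paste0("<", o, ">"),
         ifelse(is.na(o_datatype),
                paste0("\"", nt_escape(o), "\""),
                paste0("\"", nt_escape(o), "\"^^<", o_datatype, ">")))
}

#' Canonical N-Triples serialization of a graph
#'
#' Deterministic: triples are serialized and sorted so the same triple
#' set always yields byte-identical output.
#'
#' @param graph a [ProvenanceGraph-class].
#' @return a single character string (newline-terminated lines).
#' @export
canonicalNTriples <- function(graph) {
  df <- graph@triples
  if (!nrow(df)) return("")
  lines <- paste0("<", df$s, "> <", df$p, "> ",
                  nt_term_o(df$o, df$o_type, df$o_datatype), " .")
  paste0(paste(sort(lines), collapse = "\n"), "\n")
}

## ---- term scanning ---------------------------------------------------------

# Scan one RDF term from the head of `s`; returns list(term, type, datatype,
# rest) or NULL on failure. Used by the N-Triples/Turtle readers.
scan_term <- function(s, prefixes = character()) {
  s <- sub("^[ \t]+", "", s)
  if (startsWith(s, "<")) {
    end <- regexpr(">", s, fixed = TRUE)
    if (end < 0) return(NULL)
    return(list(term = substr(s, 2, end - 1), type = "iri",
                datatype = NA_character_, rest = substring(s, end + 1)))
  }
  if (startsWith(s, "\"")) {
    # find closing unescaped quote
    chars <- strsplit(s, "")[[1]]
    i <- 2L; esc <- FALSE
    while (i <= length(chars)) {
      if (esc) esc <- FALSE
      else if (chars[i] == "\\") esc <- TRUE
      else if (chars[i] == "\"") break
      i <- i + 1L
    }
    if (i > length(chars)) return(NULL)
    lex <- nt_unescape(substr(s, 2, i - 1))
    rest <- substring(s, i + 1)
    dt <- NA_character_
    if (startsWith(rest, "^^")) {
      tail <- substring(rest, 3)
      t2 <- scan_term(tail, prefixes)
      if (is.null(t2) || t2$type != "iri") return(NULL)
      dt <- t2$term
      rest <- t2$rest
    } else if (grepl("^@[A-Za-z-]+", rest)) {
      rest <- sub("^@[A-Za-z-]+", "", rest)  # language tag accepted, dropped
    }
    return(list(term = lex, type = "literal", datatype = dt, rest = rest))
  }
  if (grepl("^a([ \t]|$)", s))
    return(list(term = RDF_TYPE, type = "iri", datatype = NA_character_,
                rest = substring(s, 2)))
  m <- regmatches(s, regexpr("^([A-Za-z][A-Za-z0-9_.-]*)?:[A-Za-z0-9_.%-]*", s))
  if (length(m)) {
    pn <- m[1]
    colon <- regexpr(":", pn, fixed = TRUE)
    pre <- substr(pn, 1, colon - 1)
    local <- substring(pn, colon + 1)
    if (!pre %in% names(prefixes)) return(NULL)
    return(list(term = paste0(prefixes[[pre]], local), type = "iri",
                datatype = NA_character_, rest = substring(s, nchar(pn) + 1)))
  }
  NULL
}

parse_statement_line <- function(line, prefixes, lineno) {
  fail <- function(why)
    stop(sprintf("parse error at line %d: %s", lineno, why), call. = FALSE)
  s <- scan_term(line, prefixes)
  if (is.null(s) || s$type != "iri") fail("expected subject IRI")
  p <- scan_term(s$rest, prefixes)
  if (is.null(p) || p$type != "iri") fail("expected predicate IRI")
  o <- scan_term(p$rest, prefixes)
  if (is.null(o)) fail("expected object term")
  rest <- sub("^[ \t]+", "", o$rest)
  if (!grepl("^\\.[ \t]*$", rest)) fail("statement must end with '.'")
  tripleTable(s$term, p$term, o$term, o_type = o$type, o_datatype = o$datatype)
}

parse_lines <- function(lines, allow_prefix = TRUE, allow_graph = FALSE) {
  prefixes <- character()
  out <- list()
  depth <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (allow_prefix && grepl("^@prefix", ln)) {
      m <- regmatches(ln, regexec(
        "^@prefix[ \t]+([A-Za-z][A-Za-z0-9_.-]*)?:[ \t]+<([^>]*)>[ \t]*\\.[ \t]*$", ln))[[1]]
      if (length(m) != 3)
        stop(sprintf("parse error at line %d: malformed @prefix", i), call. = FALSE)
      prefixes[[m[2]]] <- m[3]
      next
    }
    if (allow_graph) {
      if (grepl("\\{[ \t]*$", ln)) { depth <- depth + 1L; next }
      if (grepl("^\\}[ \t]*\\.?[ \t]*$", ln)) { depth <- depth - 1L; next }
    }
    out[[length(out) + 1L]] <- parse_statement_line(ln, prefixes, i)
  }
  if (length(out)) do.call(rbind, out) else tripleTable()
}

## ---- Turtle / N-Triples writers -------------------------------------------

STD_PREFIXES <- c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS, xsd = XSD_NS)

ttl_shorten <- function(iri, prefixes) {
  for (pre in names(prefixes)) {
    ns <- prefixes[[pre]]
    if (startsWith(iri, ns)) {
      local <- substring(iri, nchar(ns) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local) && !endsWith(local, "."))
        return(paste0(pre, ":", local))
    }
  }
  paste0("<", iri, ">")
}

write_turtle <- function(graph, path) {
  df <- graph@triples
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (pre in names(STD_PREFIXES))
    writeLines(sprintf("@prefix %s: <%s> .", pre, STD_PREFIXES[[pre]]), con)
  writeLines("", con)
  if (!nrow(df)) return(invisible(path))
  sterm <- vapply(df$s, ttl_shorten, character(1), prefixes = STD_PREFIXES,
                  USE.NAMES = FALSE)
  pterm <- ifelse(df$p == RDF_TYPE, "a",
                  vapply(df$p, ttl_shorten, character(1),
                         prefixes = STD_PREFIXES, USE.NAMES = FALSE))
  oterm <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (df$o_type[i] == "iri") {
      oterm[i] <- ttl_shorten(df$o[i], STD_PREFIXES)
    } else if (is.na(df$o_datatype[i])) {
      oterm[i] <- paste0("\"", nt_escape(df$o[i]), "\"")
    } else {
      oterm[i] <- paste0("\"", nt_escape(df$o[i]), "\"^^",
                         ttl_shorten(df$o_datatype[i], STD_PREFIXES))
    }
  }
  writeLines(sort(paste(sterm, pterm, oterm, ".")), con)
  invisible(path)
}

write_ntriples <- function(graph, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sub("\n$", "", canonicalNTriples(graph)), con)
  invisible(path)
}

## ---- RDF/XML ---------------------------------------------------------------

xml_split_iri <- function(iri) {
  m <- regexpr("[#/][A-Za-z_][A-Za-z0-9_.-]*$", iri)
  if (m < 0) stop("cannot derive an XML QName for predicate IRI: ", iri)
  list(ns = substr(iri, 1, m), local = substring(iri, m + 1))
}

write_rdfxml <- function(graph, path) {
  df <- graph@triples
  pred_ns <- unique(vapply(df$p, function(p) xml_split_iri(p)$ns, character(1)))
  pred_ns <- setdiff(pred_ns, RDF_NS)
  ns_attrs <- c("xmlns:rdf" = RDF_NS)
  if (length(pred_ns)) {
    names(pred_ns) <- paste0("ns", seq_along(pred_ns))
    ns_attrs <- c(ns_attrs,
                  stats::setNames(pred_ns, paste0("xmlns:", names(pred_ns))))
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  qname <- function(p) {
    sp <- xml_split_iri(p)
    if (sp$ns == RDF_NS) paste0("rdf:", sp$local)
    else paste0(names(pred_ns)[match(sp$ns, pred_ns)], ":", sp$local)
  }
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             paste0("<rdf:RDF ",
                    paste(sprintf("%s=\"%s\"", names(ns_attrs), esc(ns_attrs)),
                          collapse = " "), ">"))
  if (nrow(df)) {
    ord <- order(df$s, df$p, df$o)
    df <- df[ord, ]
    for (subj in unique(df$s)) {
      lines <- c(lines, sprintf("  <rdf:Description rdf:about=\"%s\">", esc(subj)))
      rows <- df[df$s == subj, ]
      for (i in seq_len(nrow(rows))) {
        qn <- qname(rows$p[i])
        if (rows$o_type[i] == "iri") {
          lines <- c(lines, sprintf("    <%s rdf:resource=\"%s\"/>", qn,
                                    esc(rows$o[i])))
        } else if (is.na(rows$o_datatype[i])) {
          lines <- c(lines, sprintf("    <%s>%s</%s>", qn, esc(rows$o[i]), qn))
        } else {
          lines <- c(lines, sprintf("    <%s rdf:datatype=\"%s\">%s</%s>", qn,
                                    esc(rows$o_datatype[i]), esc(rows$o[i]), qn))
        }
      }
      lines <- c(lines, "  </rdf:Description>")
    }
  }
  lines <- c(lines, "</rdf:RDF>")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

read_rdfxml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE))
  ns_map <- xml2::xml_ns(doc)
  out <- list()
  for (node in xml2::xml_children(doc)) {
    attrs <- xml2::xml_attrs(node)
    about <- attrs[grepl("(^|:)about$", names(attrs))]
    if (!length(about)) stop("parse error: rdf:Description without rdf:about")
    subj <- about[[1]]
    for (prop in xml2::xml_children(node)) {
      qn <- xml2::xml_name(prop, ns_map)
      parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
      pred <- if (length(parts) == 2L)
        paste0(ns_map[[parts[1]]], parts[2]) else parts[1]
      pattrs <- xml2::xml_attrs(prop)
      res <- pattrs[grepl("(^|:)resource$", names(pattrs))]
      dt <- pattrs[grepl("(^|:)datatype$", names(pattrs))]
      if (length(res)) {
        out[[length(out) + 1L]] <- tripleTable(subj, pred, res[[1]])
      } else {
        out[[length(out) + 1L]] <- tripleTable(
          subj, pred, xml2::xml_text(prop), o_type = "literal",
          o_datatype = if (length(dt)) dt[[1]] else NA_character_)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else tripleTable()
}

## ---- public API ------------------------------------------------------------

infer_format <- function(path) {
  switch(tolower(sub(".*\\.", "", path)),
         ttl = "turtle", turtle = "turtle",
         nt = "ntriples", ntriples = "ntriples",
         rdf = "rdfxml", xml = "rdfxml", rdfxml = "rdfxml",
         trig = "trig",
         stop("cannot infer RDF format from path: ", path))
}

#' Write a provenance graph to disk
#'
#' N-Triples output is canonicalized (sorted) so repeated writes of the
#' same triple set are byte-identical.
#'
#' @param graph a [ProvenanceGraph-class].
#' @param path output file.
#' @param format "turtle", "ntriples" or "rdfxml"; inferred from the file
#'   extension when omitted.
#' @return the path, invisibly.
#' @export
writeGraph <- function(graph, path, format = infer_format(path)) {
  format <- match.arg(format, c("turtle", "ntriples", "rdfxml"))
  switch(format,
         turtle = write_turtle(graph, path),
         ntriples = write_ntriples(graph, path),
         rdfxml = write_rdfxml(graph, path))
  invisible(path)
}

#' Read a provenance graph from disk
#'
#' Reads Turtle (single statement per line, as written by [writeGraph()]),
#' N-Triples, RDF/XML, and TriG (named-graph blocks are collapsed into the
#' default graph). Malformed text input raises a parse error naming the
#' offending line.
#'
#' @param path input file.
#' @param format one of "turtle", "ntriples", "rdfxml", "trig"; inferred
#'   from the extension when omitted.
#' @param schema optional [OntologySchema-class] to attach to the graph.
#' @return a [ProvenanceGraph-class].
#' @export
readGraph <- function(path, format = infer_format(path), schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format, c("turtle", "ntriples", "rdfxml", "trig"))
  tt <- switch(format,
               ntriples = parse_lines(readLines(path, encoding = "UTF-8"),
                                      allow_prefix = FALSE),
               turtle = parse_lines(readLines(path, encoding = "UTF-8")),
               trig = parse_lines(readLines(path, encoding = "UTF-8"),
                                  allow_graph = TRUE),
               rdfxml = read_rdfxml(path))
  provenanceGraph(tt, schema = schema)
}
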