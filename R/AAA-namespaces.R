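# IRI vocabulary constants and helpers shared across the package.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"

RDF_TYPE      <- paste0(RDF_NS, "type")
RDF_VALUE     <- paste0(RDF_NS, "value")
RDF_STATEMENT <- paste0(RDF_NS, "Statement")
RDF_SUBJECT   <- paste0(RDF_NS, "subject")
RDF_PREDICATE <- paste0(RDF_NS, "predicate")
RDF_OBJECT    <- paste0(RDF_NS, "object")

RDFS_SUBCLASSOF    <- paste0(RDFS_NS, "subClassOf")
RDFS_SUBPROPERTYOF <- paste0(RDFS_NS, "subPropertyOf")
RDFS_DOMAIN        <- paste0(RDFS_NS, "domain")
RDFS_RANGE         <- paste0(RDFS_NS, "range")
RDFS_LABEL         <- paste0(RDFS_NS, "label")
OWL_CLASS          <- paste0(OWL_NS, "Class")
OWL_OBJECTPROPERTY <- paste0(OWL_NS, "ObjectProperty")

XSD_STRING  <- paste0(XSD_NS, "string")
XSD_INTEGER <- paste0(XSD_NS, "integer")
XSD_DECIMAL <- paste0(XSD_NS, "decimal")
XSD_DOUBLE  <- paste0(XSD_NS, "double")
XSD_DATE    <- paste0(XSD_NS, "date")
XSD_BOOLEAN <- paste0(XSD_NS, "boolean")

# Default namespace for the upper-level provenance schema and for the
# package's annotation properties (confidence scores, publication dates,
# impact factors and similar source descriptors).
PROVENIR_NS <- "http://knoesis.wright.edu/provenir/provenir.owl#"
ANNO_NS     <- "http://knoesis.wright.edu/spf/annotation#"

ANNO_CONFIDENCE   <- paste0(ANNO_NS, "confidence")
ANNO_PUB_DATE     <- paste0(ANNO_NS, "publication_date")
ANNO_YEAR         <- paste0(ANNO_NS, "year")
ANNO_IMPACTFACTOR <- paste0(ANNO_NS, "impact_factor")
ANNO_VERSION      <- paste0(ANNO_NS, "source_version")
ANNO_LABEL        <- paste0(ANNO_NS, "label")

# Vocabulary IRIs that are never treated as instance-level identifiers.
reserved_vocabulary <- function() {
  c(RDF_TYPE, RDF_VALUE, RDF_STATEMENT, RDF_SUBJECT, RDF_PREDICATE,
    RDF_OBJECT, RDFS_SUBCLASSOF, RDFS_SUBPROPERTYOF, RDFS_DOMAIN,
    RDFS_RANGE, RDFS_LABEL, OWL_CLASS, OWL_OBJECTPROPERTY)
}

REIFICATION_VOCAB <- c(RDF_STATEMENT, RDF_SUBJECT, RDF_PREDICATE, RDF_OBJECT)

#' Percent-encode an entity name for use as an IRI path segment
#'
#' Applies RFC 3986 percent-encoding to every character outside the
#' unreserved set, so the result is a single valid path segment.
#'
#' @param x character vector of raw entity names.
#' @return character vector of encoded segments.
#' @keywords internal
percent_encode <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    bytes <- charToRaw(enc2utf8(s))
    chars <- rawToChar(bytes, multiple = TRUE)
    ok <- grepl("^[A-Za-z0-9._~-]$", chars)
    chars[!ok] <- sprintf("%%%02X", as.integer(bytes[!ok]))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

percent_decode <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    utils::URLdecode(s)
  }, character(1), USE.NAMES = FALSE)
}

is_absolute_http_iri <- function(x) {
  grepl("^https?://[^[:space:]<>\"{}|\\\\^`]+$", x)
}

#' Shorten an IRI to its local name (text after the last '#' or '/')
#' @keywords internal
iri_local_name <- function(x) {
  sub(".*[#/]", "", x)
}

iri_namespace <- function(x) {
  sub("(.*[#/]).*", "\\1", x)
}
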