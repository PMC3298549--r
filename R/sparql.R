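## SPARQL composition for the query operators, and an in-memory
## evaluator for the dialect the composer emits (basic graph patterns,
## nested OPTIONAL with best-match left-join semantics, UNION, FILTER
## with comparisons and IN). The evaluator lets composed queries be
## executed against ProvenanceGraph objects without an external store;
## any SPARQL 1.1 endpoint can execute the same text.

## ---- tokenizer -------------------------------------------------------------

sparql_tokenize <- function(q) {
  tokens <- list()
  s <- q
  push <- function(type, value) tokens[[length(tokens) + 1L]] <<- list(
    type = type, value = value)
  while (nzchar(s)) {
    s <- sub("^[[:space:]]+", "", s)
    if (!nzchar(s)) break
    if (startsWith(s, "<")) {
      end <- regexpr(">", s, fixed = TRUE)
      if (end < 0) stop("SPARQL tokenizer: unterminated IRI")
      push("iri", substr(s, 2, end - 1)); s <- substring(s, end + 1); next
    }
    m <- regmatches(s, regexpr("^\\?[A-Za-z_][A-Za-z0-9_]*", s))
    if (length(m)) { push("var", substring(m, 2)); s <- substring(s, nchar(m) + 1); next }
    if (startsWith(s, "\"")) {
      chars <- strsplit(s, "")[[1]]
      i <- 2L; esc <- FALSE
      while (i <= length(chars)) {
        if (esc) esc <- FALSE
        else if (chars[i] == "\\") esc <- TRUE
        else if (chars[i] == "\"") break
        i <- i + 1L
      }
      if (i > length(chars)) stop("SPARQL tokenizer: unterminated string")
      push("lit", nt_unescape(substr(s, 2, i - 1)))
      s <- substring(s, i + 1)
      if (startsWith(s, "^^<")) {
        end <- regexpr(">", s, fixed = TRUE)
        tokens[[length(tokens)]]$datatype <- substr(s, 4, end - 1)
        s <- substring(s, end + 1)
      }
      next
    }
    m <- regmatches(s, regexpr("^-?[0-9]+(\\.[0-9]+)?", s))
    if (length(m)) { push("num", m); s <- substring(s, nchar(m) + 1); next }
    m <- regmatches(s, regexpr("^[A-Za-z_][A-Za-z0-9_]*", s))
    if (length(m)) { push("kw", toupper(m)); s <- substring(s, nchar(m) + 1); next }
    two <- substr(s, 1, 2)
    if (two %in% c(">=", "<=", "!=", "&&", "||")) {
      push("op", two); s <- substring(s, 3); next
    }
    one <- substr(s, 1, 1)
    if (one %in% c("{", "}", "(", ")", ",", ".", "=", ">", "<")) {
      push(if (one %in% c("=", ">", "<")) "op" else "punct", one)
      s <- substring(s, 2); next
    }
    stop("SPARQL tokenizer: unexpected input near: ", substr(s, 1, 30))
  }
  tokens
}

new_token_stream <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens; env$pos <- 1L
  env
}
ts_peek <- function(ts) if (ts$pos <= length(ts$tokens)) ts$tokens[[ts$pos]] else NULL
ts_take <- function(ts) { tk <- ts_peek(ts); ts$pos <- ts$pos + 1L; tk }
ts_expect <- function(ts, type, value = NULL) {
  tk <- ts_take(ts)
  if (is.null(tk) || tk$type != type ||
      (!is.null(value) && !identical(tk$value, value)))
    stop("SPARQL parse error: expected ", value %||% type, " got ",
         if (is.null(tk)) "end of input" else tk$value)
  tk
}

## ---- parser ----------------------------------------------------------------

parse_sparql <- function(query) {
  ts <- new_token_stream(sparql_tokenize(query))
  head_tk <- ts_expect(ts, "kw")
  if (head_tk$value == "SELECT") {
    distinct <- FALSE
    if (!is.null(ts_peek(ts)) && ts_peek(ts)$type == "kw" &&
        ts_peek(ts)$value == "DISTINCT") { ts_take(ts); distinct <- TRUE }
    vars <- character()
    while (!is.null(ts_peek(ts)) && ts_peek(ts)$type == "var")
      vars <- c(vars, ts_take(ts)$value)
    ts_expect(ts, "kw", "WHERE")
    grp <- parse_sparql_group(ts)
    list(form = "select", vars = vars, distinct = distinct, group = grp)
  } else if (head_tk$value == "ASK") {
    if (!is.null(ts_peek(ts)) && ts_peek(ts)$type == "kw" &&
        ts_peek(ts)$value == "WHERE") ts_take(ts)
    grp <- parse_sparql_group(ts)
    list(form = "ask", group = grp)
  } else stop("SPARQL parse error: expected SELECT or ASK")
}

parse_sparql_group <- function(ts) {
  ts_expect(ts, "punct", "{")
  items <- list()
  repeat {
    tk <- ts_peek(ts)
    if (is.null(tk)) stop("SPARQL parse error: unterminated group")
    if (tk$type == "punct" && tk$value == "}") { ts_take(ts); break }
    if (tk$type == "kw" && tk$value == "OPTIONAL") {
      ts_take(ts)
      items[[length(items) + 1L]] <- list(kind = "optional",
                                          group = parse_sparql_group(ts))
    } else if (tk$type == "kw" && tk$value == "FILTER") {
      ts_take(ts)
      ts_expect(ts, "punct", "(")
      items[[length(items) + 1L]] <- list(kind = "filter",
                                          expr = parse_filter_expr(ts))
      ts_expect(ts, "punct", ")")
    } else if (tk$type == "punct" && tk$value == "{") {
      branches <- list(parse_sparql_group(ts))
      while (!is.null(ts_peek(ts)) && ts_peek(ts)$type == "kw" &&
             ts_peek(ts)$value == "UNION") {
        ts_take(ts)
        branches[[length(branches) + 1L]] <- parse_sparql_group(ts)
      }
      items[[length(items) + 1L]] <-
        if (length(branches) == 1L) list(kind = "group", group = branches[[1]])
        else list(kind = "union", branches = branches)
    } else {
      s <- parse_term(ts); p <- parse_term(ts); o <- parse_term(ts)
      ts_expect(ts, "punct", ".")
      items[[length(items) + 1L]] <- list(kind = "tp", s = s, p = p, o = o)
    }
  }
  items
}

parse_term <- function(ts) {
  tk <- ts_take(ts)
  if (is.null(tk)) stop("SPARQL parse error: expected term")
  if (tk$type == "kw" && tk$value == "A")
    return(list(kind = "iri", value = RDF_TYPE))
  switch(tk$type,
         iri = list(kind = "iri", value = tk$value),
         var = list(kind = "var", value = tk$value),
         lit = list(kind = "lit", value = tk$value,
                    datatype = tk$datatype %||% NA_character_),
         num = list(kind = "num", value = as.numeric(tk$value)),
         stop("SPARQL parse error: unexpected token ", tk$value))
}

parse_filter_expr <- function(ts) {
  conds <- list(parse_filter_cond(ts))
  while (!is.null(ts_peek(ts)) && ts_peek(ts)$type == "op" &&
         ts_peek(ts)$value == "&&") {
    ts_take(ts)
    conds[[length(conds) + 1L]] <- parse_filter_cond(ts)
  }
  if (length(conds) == 1L) conds[[1]] else list(kind = "and", conds = conds)
}

parse_filter_cond <- function(ts) {
  v <- ts_expect(ts, "var")$value
  tk <- ts_take(ts)
  if (tk$type == "kw" && tk$value == "IN") {
    ts_expect(ts, "punct", "(")
    vals <- list()
    repeat {
      vals[[length(vals) + 1L]] <- parse_term(ts)
      nxt <- ts_take(ts)
      if (nxt$type == "punct" && nxt$value == ")") break
      if (!(nxt$type == "punct" && nxt$value == ","))
        stop("SPARQL parse error: expected , or ) in IN list")
    }
    return(list(kind = "in", var = v, values = vals))
  }
  if (tk$type != "op") stop("SPARQL parse error: expected comparator")
  rhs <- parse_term(ts)
  list(kind = "cmp", var = v, op = tk$value, rhs = rhs)
}

## ---- evaluator -------------------------------------------------------------

# Solutions are named character vectors (variable -> bound value).
eval_sparql_group <- function(items, rows, df) {
  for (item in items) {
    rows <- switch(item$kind,
      tp = {
        out <- lapply(rows, function(r) match_triple_pattern(r, item, df))
        do.call(c, c(list(list()), out))
      },
      optional = {
        out <- lapply(rows, function(r) {
          ext <- eval_sparql_group(item$group, list(r), df)
          if (length(ext)) ext else list(r)
        })
        do.call(c, c(list(list()), out))
      },
      group = eval_sparql_group(item$group, rows, df),
      union = {
        out <- lapply(rows, function(r) {
          do.call(c, c(list(list()), lapply(item$branches, function(b)
            eval_sparql_group(b, list(r), df))))
        })
        do.call(c, c(list(list()), out))
      },
      filter = Filter(function(r) eval_filter(item$expr, r), rows),
      stop("unknown pattern item kind: ", item$kind))
    if (!length(rows)) return(rows)
  }
  rows
}

match_triple_pattern <- function(r, tp, df) {
  resolve <- function(term) {
    if (term$kind == "var" && term$value %in% names(r))
      list(kind = "bound", value = r[[term$value]])
    else term
  }
  s <- resolve(tp$s); p <- resolve(tp$p); o <- resolve(tp$o)
  mask <- rep(TRUE, nrow(df))
  if (s$kind != "var") mask <- mask & df$s == s$value
  if (p$kind != "var") mask <- mask & df$p == p$value
  if (o$kind %in% c("iri", "bound")) {
    mask <- mask & df$o == o$value
  } else if (o$kind == "lit") {
    mask <- mask & df$o_type == "literal" & df$o == o$value
  } else if (o$kind == "num") {
    onum <- suppressWarnings(as.numeric(df$o))
    mask <- mask & df$o_type == "literal" & !is.na(onum) & onum == o$value
  }
  hits <- which(mask)
  out <- vector("list", length(hits))
  j <- 0L
  for (i in hits) {
    r2 <- r
    ok <- TRUE
    for (slot in list(list(tp$s, df$s[i]), list(tp$p, df$p[i]),
                      list(tp$o, df$o[i]))) {
      term <- slot[[1]]
      if (term$kind == "var") {
        if (term$value %in% names(r2)) {
          if (!identical(r2[[term$value]], slot[[2]])) { ok <- FALSE; break }
        } else r2[[term$value]] <- slot[[2]]
      }
    }
    if (ok) { j <- j + 1L; out[[j]] <- r2 }
  }
  out[seq_len(j)]
}

eval_filter <- function(expr, r) {
  switch(expr$kind,
    and = all(vapply(expr$conds, eval_filter, logical(1), r = r)),
    "in" = {
      if (!expr$var %in% names(r)) return(FALSE)
      v <- r[[expr$var]]
      any(vapply(expr$values, function(t) identical(t$value, v), logical(1)))
    },
    cmp = {
      if (!expr$var %in% names(r)) return(FALSE)
      v <- r[[expr$var]]
      rhs <- expr$rhs
      if (rhs$kind == "num") {
        vn <- suppressWarnings(as.numeric(v))
        if (is.na(vn)) return(FALSE)
        switch(expr$op, "=" = vn == rhs$value, "!=" = vn != rhs$value,
               ">" = vn > rhs$value, "<" = vn < rhs$value,
               ">=" = vn >= rhs$value, "<=" = vn <= rhs$value)
      } else {
        switch(expr$op, "=" = identical(v, rhs$value),
               "!=" = !identical(v, rhs$value),
               stop("ordering comparator needs a numeric operand"))
      }
    },
    stop("unknown filter kind"))
}

#' Execute a SPARQL query against a provenance graph
#'
#' Supports the dialect emitted by [composeSparql()] and the closure
#' probes: `SELECT [DISTINCT]` and `ASK` forms over basic graph patterns
#' with nested `OPTIONAL` (best-match left joins), `UNION`, and `FILTER`
#' with comparison and `IN` expressions. Variable bindings are returned
#' as a data.frame (unbound = `NA`).
#'
#' @param query SPARQL query text.
#' @param graph a [ProvenanceGraph-class].
#' @return for SELECT, `list(form="select", vars, bindings)`; for ASK,
#'   `list(form="ask", boolean)`.
#' @export
executeSparql <- function(query, graph) {
  ast <- parse_sparql(query)
  rows <- eval_sparql_group(ast$group, list(stats::setNames(list(), character())),
                            graph@triples)
  if (ast$form == "ask")
    return(list(form = "ask", boolean = length(rows) > 0))
  vars <- if (length(ast$vars)) ast$vars
          else sort(unique(unlist(lapply(rows, names))))
  cols <- lapply(vars, function(v)
    vapply(rows, function(r) if (v %in% names(r)) r[[v]] else NA_character_,
           character(1)))
  bindings <- as.data.frame(stats::setNames(cols, vars),
                            stringsAsFactors = FALSE, optional = TRUE)
  if (isTRUE(ast$distinct)) bindings <- unique(bindings)
  rownames(bindings) <- NULL
  list(form = "select", vars = vars, bindings = bindings)
}

## ---- query metrics ---------------------------------------------------------

count_ast <- function(items, depth = 0L) {
  vars <- character(); tp <- 0L; maxd <- depth
  for (item in items) {
    if (item$kind == "tp") {
      tp <- tp + 1L
      for (t in list(item$s, item$p, item$o))
        if (t$kind == "var") vars <- c(vars, t$value)
    } else if (item$kind == "optional") {
      sub <- count_ast(item$group, depth + 1L)
      vars <- c(vars, sub$vars); tp <- tp + sub$tp
      maxd <- max(maxd, sub$maxd)
    } else if (item$kind %in% c("group")) {
      sub <- count_ast(item$group, depth)
      vars <- c(vars, sub$vars); tp <- tp + sub$tp
      maxd <- max(maxd, sub$maxd)
    } else if (item$kind == "union") {
      for (b in item$branches) {
        sub <- count_ast(b, depth)
        vars <- c(vars, sub$vars); tp <- tp + sub$tp
        maxd <- max(maxd, sub$maxd)
      }
    } else if (item$kind == "filter") {
      vars <- c(vars, filter_vars(item$expr))
    }
  }
  list(vars = vars, tp = tp, maxd = maxd)
}

filter_vars <- function(expr) {
  switch(expr$kind,
         and = unlist(lapply(expr$conds, filter_vars)),
         "in" = expr$var, cmp = expr$var)
}

#' Structural metrics of a SPARQL query
#'
#' Query complexity is measured by the number of distinct variables, the
#' number of triple patterns, and the maximal OPTIONAL nesting depth.
#'
#' @param query SPARQL text (the [composeSparql()] dialect).
#' @return list with `variable_count`, `triple_count`, `nesting_depth`.
#' @export
queryPatternMetrics <- function(query) {
  ast <- parse_sparql(query)
  cnt <- count_ast(ast$group)
  list(variable_count = length(unique(cnt$vars)),
       triple_count = cnt$tp, nesting_depth = cnt$maxd)
}

## ---- composition -----------------------------------------------------------

iri_term <- function(x) paste0("<", x, ">")

# predicate position: single IRI directly, several (subproperty expansion)
# via a predicate variable plus an IN filter.
pred_pattern <- function(subj, uris, obj, var) {
  if (length(uris) == 1L)
    list(tp = sprintf("%s %s %s .", subj, iri_term(uris), obj),
         filter = NULL)
  else
    list(tp = sprintf("%s ?%s %s .", subj, var, obj),
         filter = sprintf("FILTER(?%s IN (%s))", var,
                          paste(iri_term(uris), collapse = ", ")))
}

indent <- function(lines, n) paste0(strrep("  ", n), lines)

# Component bindings (agent / participant / parameter) of one process
# variable, each in its own OPTIONAL block so absent components shrink
# the answer instead of failing the branch (best-match semantics).
compose_component_blocks <- function(pvar, tag, schema) {
  roles <- list(c("has_agent", "a"), c("has_participant", "t"),
                c("has_parameter", "m"))
  out <- character()
  for (rl in roles) {
    uris <- role_property_uris(schema, rl[1])
    v <- paste0(rl[2], tag)
    pp <- pred_pattern(paste0("?", pvar), uris, paste0("?", v),
                       paste0("pr", v))
    out <- c(out, paste("OPTIONAL {", pp$tp,
                        if (!is.null(pp$filter)) pp$filter, "}"))
  }
  out
}

# The provenance() template is a UNION over depth-limited chains: one
# branch per (derivation depth i, process-chain depth j) pair, each a
# linear path from the entity with the terminal process's components in
# OPTIONAL blocks. Every chain prefix has its own branch, so partially
# recorded provenance still matches (the result shrinks, the query never
# fails), while the result multiset stays linear in the closure depths.
compose_provenance <- function(entity, schema, dDepth, pDepth) {
  dfp <- role_property_uris(schema, "derives_from")
  hp <- role_property_uris(schema, "has_participant")
  pb <- role_property_uris(schema, "preceded_by")
  d_chain <- function(i) {
    if (!i) return(character())
    unlist(lapply(seq_len(i), function(k) {
      subj <- if (k == 1L) iri_term(entity) else sprintf("?d%d", k - 1L)
      pp <- pred_pattern(subj, dfp, sprintf("?d%d", k), sprintf("prd%d", k))
      c(pp$tp, pp$filter)
    }))
  }
  branches <- list()
  for (i in 0:dDepth) {
    base <- d_chain(i)
    d_term <- if (!i) iri_term(entity) else sprintf("?d%d", i)
    if (i > 0L) branches[[length(branches) + 1L]] <- base
    for (j in 0:pDepth) {
      tag <- sprintf("%d_%d", i, j)
      pv <- function(k) sprintf("p%s_%d", tag, k)
      pp0 <- pred_pattern(paste0("?", pv(0L)), hp, d_term,
                          paste0("prh", tag))
      lines <- c(base, pp0$tp, pp0$filter)
      for (k in seq_len(j)) {
        ppk <- pred_pattern(paste0("?", pv(k - 1L)), pb,
                            paste0("?", pv(k)), sprintf("prb%s_%d", tag, k))
        lines <- c(lines, ppk$tp, ppk$filter)
      }
      lines <- c(lines, compose_component_blocks(pv(j), tag, schema))
      branches[[length(branches) + 1L]] <- lines
    }
  }
  btxt <- vapply(branches, function(b)
    paste0("  { ", paste(b, collapse = " "), " }"), character(1))
  body <- paste(btxt, collapse = " UNION\n")
  probe <- paste(c("SELECT ?probe WHERE {", body, "}"), collapse = "\n")
  vars <- setdiff(sort(unique(count_ast(parse_sparql(probe)$group)$vars)),
                  "probe")
  vars <- vars[!grepl("^pr", vars)]   # predicate-expansion helper variables
  paste(c(sprintf("SELECT DISTINCT %s WHERE {",
                  paste0("?", vars, collapse = " ")),
          body, "}"), collapse = "\n")
}

compose_context_query <- function(constraints, schema, dDepth) {
  dc_uris <- class_uri(schema, subclassesOf(schema, "data_collection"))
  dfp <- role_property_uris(schema, "derives_from")
  hp <- role_property_uris(schema, "has_participant")
  hpm <- role_property_uris(schema, "has_parameter")
  lines <- c("  ?e <" %+% RDF_TYPE %+% "> ?c0 .",
             sprintf("  FILTER(?c0 IN (%s))",
                     paste(iri_term(dc_uris), collapse = ", ")))
  for (i in seq_along(constraints)) {
    con <- constraints[[i]]
    tg <- resolve_constraint_target(schema, con@target)
    vv <- sprintf("v%d", i)
    mk_leaf <- function(subj) {
      if (tg$kind == "property") {
        if (length(tg$uris) == 1L)
          sprintf("%s <%s> ?%s .", subj, tg$uris, vv)
        else c(sprintf("%s ?pc%d ?%s .", subj, i, vv),
               sprintf("FILTER(?pc%d IN (%s))", i,
                       paste(iri_term(tg$uris), collapse = ", ")))
      } else {
        c(sprintf("%s <%s> ?%s .", subj, RDF_TYPE, vv),
          sprintf("FILTER(?%s IN (%s))", vv,
                  paste(iri_term(tg$uris), collapse = ", ")))
      }
    }
    branches <- list(mk_leaf("?e"))
    chain <- character(); prev <- "?e"
    for (k in seq_len(dDepth)) {
      xv <- sprintf("x%d_%d", i, k)
      chain <- c(chain, {
        pp <- pred_pattern(prev, dfp, paste0("?", xv), sprintf("pd%d_%d", i, k))
        c(pp$tp, pp$filter)
      })
      branches[[length(branches) + 1L]] <- c(chain, mk_leaf(paste0("?", xv)))
      prev <- paste0("?", xv)
    }
    # creating-process parameters
    pvar <- sprintf("q%d", i); mvar <- sprintf("w%d", i)
    pp1 <- pred_pattern(paste0("?", pvar), hp, "?e", sprintf("ph%d", i))
    pp2 <- pred_pattern(paste0("?", pvar), hpm, paste0("?", mvar),
                        sprintf("pm%d", i))
    branches[[length(branches) + 1L]] <-
      c(pp1$tp, pp1$filter, pp2$tp, pp2$filter, mk_leaf(paste0("?", mvar)))
    btxt <- vapply(branches, function(b)
      paste0("{ ", paste(b, collapse = " "), " }"), character(1))
    lines <- c(lines, paste0("  ", paste(btxt, collapse = " UNION ")))
    if (tg$kind == "property") {
      cmp <- switch(con@comparator, contains = NULL, con@comparator)
      if (is.null(cmp))
        stop("composition error: 'contains' constraints are not composable")
      rhs <- if (is.numeric(con@value))
        format(con@value, scientific = FALSE, trim = TRUE)
      else paste0("\"", nt_escape(as.character(con@value)), "\"")
      lines <- c(lines, sprintf("  FILTER(?%s %s %s)", vv, cmp, rhs))
    }
  }
  paste(c("SELECT DISTINCT ?e WHERE {", lines, "}"), collapse = "\n")
}

`%+%` <- function(a, b) paste0(a, b)

compose_pattern_query <- function(pattern, schema) {
  el <- pattern@elements
  if (!nrow(el)) stop("composition error: empty pattern")
  lines <- character()
  for (i in seq_len(nrow(el))) {
    nv <- sprintf("n%d", i)
    cls <- subclassesOf(schema, el$class[i])
    uris <- class_uri(schema, cls)
    if (length(uris) == 1L) {
      lines <- c(lines, sprintf("  ?%s <%s> %s .", nv, RDF_TYPE,
                                iri_term(uris)))
    } else {
      cv <- sprintf("c%d", i)
      lines <- c(lines, sprintf("  ?%s <%s> ?%s .", nv, RDF_TYPE, cv),
                 sprintf("  FILTER(?%s IN (%s))", cv,
                         paste(iri_term(uris), collapse = ", ")))
    }
    if (i > 1L) {
      pp <- pred_pattern(sprintf("?n%d", i - 1L),
                         role_property_uris(schema, el$property[i]),
                         paste0("?", nv), sprintf("lp%d", i))
      lines <- c(lines, paste0("  ", pp$tp),
                 if (!is.null(pp$filter)) paste0("  ", pp$filter))
    }
  }
  vars <- paste0("?n", seq_len(nrow(el)), collapse = " ")
  paste(c(sprintf("SELECT DISTINCT %s WHERE {", vars), lines, "}"),
        collapse = "\n")
}

#' Compose a SPARQL query for a provenance query operator
#'
#' Maps a query operator to SPARQL text: classes are expanded to their
#' subclass sets and properties to their subproperty sets per RDFS
#' entailment, provenance components are wrapped in OPTIONAL blocks
#' (nested per closure depth) so the query succeeds with partial
#' instantiation, and structural metrics of the emitted pattern are
#' returned alongside the text.
#'
#' Operators: `"provenance"` (input: entity IRI), `"provenance_context"`
#' (input: list of [ProvenanceConstraint-class]), `"pattern"` (input: a
#' [ProvenancePattern-class]), `"transitive_closure"` (input:
#' `list(start=, property=, depth=)`; emits the depth-`depth` ASK probe).
#'
#' @param operator operator name (above).
#' @param input operator input value.
#' @param schema an [OntologySchema-class].
#' @param dDepth unrolled derivation-chain depth.
#' @param pDepth unrolled process-chain (`preceded_by`) closure depth.
#' @return list with `query` (text) and `metrics`
#'   (see [queryPatternMetrics()]).
#' @export
composeSparql <- function(operator, input, schema, dDepth = 4L, pDepth = 6L) {
  query <- switch(operator,
    provenance = compose_provenance(input, schema, dDepth, pDepth),
    provenance_context = compose_context_query(input, schema, dDepth),
    pattern = compose_pattern_query(input, schema),
    transitive_closure = closure_probe_query(
      input$start,
      role_property_uris(schema, input$property %||% "preceded_by"),
      input$depth %||% 1L)$ask,
    stop("composition error: unknown operator '", operator, "'"))
  list(query = query, metrics = queryPatternMetrics(query))
}

#' Instance nodes named by a composed provenance query's results
#'
#' Helper for cross-validating composed SPARQL against the direct
#' [provenance()] operator: collects every IRI bound in the result
#' bindings together with the root entity.
#'
#' @param result an [executeSparql()] SELECT result.
#' @param entity the root entity IRI.
#' @return sorted character vector of IRIs.
#' @export
sparqlResultNodes <- function(result, entity) {
  vals <- unlist(result$bindings, use.names = FALSE)
  sort(unique(c(entity, vals[!is.na(vals)])))
}

#' Instance nodes of a provenance subgraph
#'
#' The counterpart of [sparqlResultNodes()] on the direct operator's
#' output: the subgraph's nodes minus schema vocabulary.
#'
#' @param graph a [ProvenanceGraph-class] returned by [provenance()].
#' @return sorted character vector of IRIs.
#' @export
provenanceNodes <- function(graph) {
  schema <- graph@schema
  vocab <- if (!is.null(schema)) c(schema@classes$uri, schema@properties$uri)
           else character()
  sort(setdiff(graphNodes(graph), vocab))
}
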