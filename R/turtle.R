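# Turtle serialization of the schema (T-Box) and person profiles (A-Box).
#
# A constrained, deterministic dialect: one triple per line, sorted schema
# block, reified assertion statements (baseline RDF 1.1 reification, no
# RDF-star) carrying wave/provenance/rule-id annotations alongside the
# direct person-to-object triple. Imports accept exactly this dialect.

TTL_PREFIXES <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  cco  = "http://example.org/cco#",
  person = "http://example.org/person/",
  stmt = "http://example.org/statement/"
)

ttl_lit <- function(x, type = NULL) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub('"', '\\\\"', x)
  if (is.null(type)) sprintf('"%s"', x) else sprintf('"%s"^^%s', x, type)
}

#' Export schema and/or profiles to Turtle
#'
#' Concepts become `owl:Class` nodes with `rdfs:subClassOf`/`rdfs:label`
#' triples, relations become `owl:ObjectProperty`/`owl:DatatypeProperty`
#' nodes with domain/range (the dual `hasAffect` yields two range triples),
#' and each profile assertion is written both as a direct triple and as a
#' reified `rdf:Statement` carrying its wave, provenance and rule id.
#' Output triple order is deterministic, so exports diff cleanly.
#'
#' @param schema optional `cco_schema`.
#' @param profiles optional `person_profile` or list of them.
#' @param path optional output file.
#' @return (invisibly) the Turtle document as a character vector of lines.
#' @export
export_turtle <- function(schema = NULL, profiles = NULL, path = NULL) {
  lines <- sprintf("@prefix %s: <%s> .", names(TTL_PREFIXES), TTL_PREFIXES)
  body <- character(0)
  if (!is.null(schema)) {
    tb <- character(0)
    for (co in schema$concepts) {
      tb <- c(tb,
        sprintf("%s rdf:type owl:Class .", co$id),
        sprintf("%s rdfs:label %s .", co$id, ttl_lit(co$label)),
        sprintf("%s cco:source %s .", co$id, ttl_lit(co$source)),
        sprintf("%s rdfs:subClassOf %s .", co$id, co$parents),
        if (!is.null(co$factor))
          sprintf("%s cco:factor %s .", co$id, ttl_lit(co$factor)))
    }
    for (r in schema$relations) {
      subj <- paste0("cco:", r$name)
      ptype <- if (r$range_kind %in% c("text", "date"))
        "owl:DatatypeProperty" else "owl:ObjectProperty"
      rng <- switch(r$range_kind,
        concept = r$range, coordinate = "cco:coordinate",
        text = "xsd:string", date = "xsd:date")
      tb <- c(tb,
        sprintf("%s rdf:type %s .", subj, ptype),
        sprintf("%s rdfs:domain cco:person .", subj),
        sprintf("%s rdfs:range %s .", subj, rng),
        sprintf("%s cco:factor %s .", subj, ttl_lit(r$factor)),
        sprintf("%s cco:source %s .", subj, ttl_lit(r$source)),
        if (r$functional) sprintf("%s cco:functional \"true\" .", subj),
        if (!is.null(r$parent))
          sprintf("%s rdfs:subPropertyOf cco:%s .", subj, r$parent))
    }
    for (base in names(schema$constraints$level_vocab)) {
      vocab <- schema$constraints$level_vocab[[base]]
      tb <- c(tb,
        sprintf("%s cco:levelBase %s .", vocab, base),
        sprintf("%s cco:levelRank %s .", vocab,
                ttl_lit(seq_along(vocab), "xsd:integer")))
    }
    for (p in schema$constraints$disjoint) {
      tb <- c(tb, sprintf("%s owl:disjointWith %s .", p[1], p[2]))
    }
    body <- c(body, sort(tb))
  }
  if (!is.null(profiles)) {
    if (inherits(profiles, "person_profile")) profiles <- list(profiles)
    ids <- vapply(profiles, `[[`, "", "id")
    for (p in profiles[order(ids)]) {
      subj <- paste0("person:", p$id)
      body <- c(body, sprintf("%s rdf:type cco:person .", subj))
      a <- p$assertions
      for (i in seq_len(nrow(a))) {
        obj <- switch(a$object_kind[i],
          concept = a$object[i],
          coordinate = ttl_lit(a$object[i], "cco:coordinate"),
          date = ttl_lit(a$object[i], "xsd:date"),
          text = ttl_lit(a$object[i]))
        node <- sprintf("stmt:%s-%d", p$id, i)
        body <- c(body,
          sprintf("%s cco:%s %s .", subj, a$relation[i], obj),
          sprintf("%s rdf:type rdf:Statement .", node),
          sprintf("%s rdf:subject %s .", node, subj),
          sprintf("%s rdf:predicate cco:%s .", node, a$relation[i]),
          sprintf("%s rdf:object %s .", node, obj),
          sprintf("%s cco:wave %s .", node, ttl_lit(a$wave[i])),
          sprintf("%s cco:provenance %s .", node, ttl_lit(a$provenance[i])),
          if (!is.na(a$value[i]))
            sprintf("%s cco:value %s .", node, ttl_lit(a$value[i])),
          if (!is.na(a$rule_id[i]))
            sprintf("%s cco:ruleId %s .", node, ttl_lit(a$rule_id[i])))
      }
    }
  }
  lines <- c(lines, body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# tokenize one triple line of the constrained dialect into its three terms
ttl_parse_line <- function(line, lineno) {
  s <- trimws(line)
  s <- sub("\\s*\\.\\s*$", "", s)
  terms <- list(); i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == '"') {
      j <- i + 1L
      while (j <= n) {
        cj <- substr(s, j, j)
        if (cj == "\\") { j <- j + 2L; next }
        if (cj == '"') break
        j <- j + 1L
      }
      if (j > n) {
        stop_psychonto(sprintf("unterminated literal at line %d", lineno),
                       "psychonto_parse_error")
      }
      val <- substr(s, i + 1L, j - 1L)
      val <- gsub('\\\\"', '"', val)
      val <- gsub("\\\\\\\\", "\\\\", val)
      type <- NULL
      if (substr(s, j + 1L, j + 2L) == "^^") {
        k <- j + 3L
        while (k <= n && !grepl("^\\s$", substr(s, k, k))) k <- k + 1L
        type <- substr(s, j + 3L, k - 1L)
        j <- k - 1L
      }
      terms[[length(terms) + 1L]] <- list(kind = "literal", value = val,
                                          type = type)
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !grepl("^\\s$", substr(s, j, j))) j <- j + 1L
      tok <- substr(s, i, j - 1L)
      if (!grepl("^[A-Za-z][A-Za-z0-9]*:", tok)) {
        stop_psychonto(sprintf("malformed term '%s' at line %d", tok, lineno),
                       "psychonto_parse_error")
      }
      pfx <- sub(":.*$", "", tok)
      if (!pfx %in% names(TTL_PREFIXES)) {
        stop_psychonto(sprintf("unknown prefix '%s' at line %d", pfx, lineno),
                       "psychonto_vocabulary_error")
      }
      terms[[length(terms) + 1L]] <- list(kind = "qname", value = tok)
      i <- j
    }
  }
  if (length(terms) != 3L) {
    stop_psychonto(sprintf("expected 3 terms at line %d: '%s'", lineno, line),
                   "psychonto_parse_error")
  }
  terms
}

#' Import a Turtle document
#'
#' Parses the dialect written by [export_turtle()]: rebuilds the schema when
#' class/property triples are present and person profiles from reified
#' assertion statements (the authoritative carriers of wave and provenance,
#' so the assertion multiset round-trips exactly).
#'
#' @param x path to a Turtle file or a character vector of lines.
#' @param schema optional `cco_schema` used to validate profiles when the
#'   document carries no T-Box of its own.
#' @return list with `schema` (or `NULL`) and `profiles` (possibly empty
#'   named list).
#' @export
import_turtle <- function(x, schema = NULL) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  triples <- list()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[[ln]])
    if (!nzchar(s) || startsWith(s, "#")) next
    if (startsWith(s, "@prefix")) {
      m <- regmatches(s, regexec("^@prefix\\s+([A-Za-z]+):\\s+<([^>]*)>", s))[[1]]
      if (length(m) == 0L) {
        stop_psychonto(sprintf("malformed @prefix at line %d", ln),
                       "psychonto_parse_error")
      }
      next
    }
    triples[[length(triples) + 1L]] <- ttl_parse_line(s, ln)
  }
  subj <- vapply(triples, function(t) t[[1]]$value, "")
  pred <- vapply(triples, function(t) t[[2]]$value, "")
  ovals <- vapply(triples, function(t) t[[3]]$value, "")
  okind <- vapply(triples, function(t) t[[3]]$kind, "")
  otype <- vapply(triples, function(t) t[[3]]$type %||% "", "")

  out_schema <- schema
  classes <- unique(subj[pred == "rdf:type" & ovals == "owl:Class"])
  if (length(classes)) {
    out_schema <- ontology_schema()
    info <- lapply(classes, function(cid) {
      list(id = cid,
           label = ovals[subj == cid & pred == "rdfs:label"][1],
           source = ovals[subj == cid & pred == "cco:source"][1],
           parents = ovals[subj == cid & pred == "rdfs:subClassOf"],
           factor = {
             f <- ovals[subj == cid & pred == "cco:factor"]
             if (length(f)) f else NULL
           })
    })
    names(info) <- classes
    pending <- classes
    while (length(pending)) {
      ready <- Filter(function(cid)
        all(info[[cid]]$parents %in% names(out_schema$concepts)), pending)
      if (length(ready) == 0L) {
        stop_psychonto("unresolvable subclass references (cycle or missing parent)",
                       "psychonto_parse_error")
      }
      for (cid in ready) {
        ci <- info[[cid]]
        out_schema <- add_concept(out_schema, ci$label, ci$parents,
                                  source = ci$source, factor = ci$factor,
                                  id = ci$id)
      }
      pending <- setdiff(pending, ready)
    }
    props <- unique(subj[pred == "rdf:type" &
                           ovals %in% c("owl:ObjectProperty",
                                        "owl:DatatypeProperty")])
    # declare parents (super-properties) first
    pparent <- vapply(props, function(pr) {
      v <- ovals[subj == pr & pred == "rdfs:subPropertyOf"]
      if (length(v)) v[1] else NA_character_
    }, "")
    for (pr in props[order(!is.na(pparent))]) {
      name <- sub("^cco:", "", pr)
      rngs <- ovals[subj == pr & pred == "rdfs:range"]
      fac <- ovals[subj == pr & pred == "cco:factor"][1]
      src <- ovals[subj == pr & pred == "cco:source"][1]
      fun <- any(subj == pr & pred == "cco:functional")
      par <- if (!is.na(pparent[[pr]])) sub("^cco:", "", pparent[[pr]]) else NULL
      for (rng in rngs) {
        kind <- if (rng == "xsd:string") "text"
          else if (rng == "xsd:date") "date"
          else if (rng == "cco:coordinate") "coordinate"
          else "concept"
        out_schema <- add_relation(out_schema, name,
                                   if (kind == "concept") rng else kind,
                                   factor = fac, functional = fun,
                                   parent = par, source = src,
                                   range_kind = kind)
      }
    }
    lv <- which(pred == "cco:levelBase")
    for (base in unique(ovals[lv])) {
      members <- subj[lv][ovals[lv] == base]
      ranks <- vapply(members, function(m)
        as.integer(ovals[subj == m & pred == "cco:levelRank"][1]), 0L)
      out_schema$constraints$level_vocab[[base]] <- members[order(ranks)]
    }
    dj <- which(pred == "owl:disjointWith")
    for (i in dj) {
      out_schema <- add_disjoint(out_schema, subj[i], ovals[i])
    }
    validate_schema(out_schema)
  }

  profiles <- list()
  persons <- unique(subj[pred == "rdf:type" & ovals == "cco:person"])
  if (length(persons) && is.null(out_schema)) {
    stop_psychonto("profiles present but no schema available",
                   "psychonto_parse_error")
  }
  for (pid_iri in persons) {
    pid <- sub("^person:", "", pid_iri)
    prof <- person_profile(pid)
    nodes <- unique(subj[pred == "rdf:subject" & ovals == pid_iri])
    idx <- as.integer(sub(".*-(\\d+)$", "\\1", nodes))
    for (node in nodes[order(idx)]) {
      sel <- function(p) {
        i <- which(subj == node & pred == p)
        if (length(i)) list(value = ovals[i[1]], kind = okind[i[1]],
                            type = otype[i[1]]) else NULL
      }
      rel <- sub("^cco:", "", sel("rdf:predicate")$value)
      ob <- sel("rdf:object")
      wave <- sel("cco:wave")$value
      prov <- sel("cco:provenance")$value
      val <- sel("cco:value")
      rid <- sel("cco:ruleId")
      object <- if (ob$kind == "qname") {
        ob$value
      } else if (identical(ob$type, "cco:coordinate")) {
        xs <- as.numeric(strsplit(ob$value, ",")[[1]])
        coordinate(xs[1], xs[2])
      } else {
        ob$value
      }
      prof <- assert_fact(prof, out_schema, rel, object, wave = wave,
                          provenance = prov,
                          value = if (is.null(val)) NA_character_ else val$value,
                          rule_id = if (is.null(rid)) NA_character_ else rid$value)
    }
    profiles[[pid]] <- prof
  }
  list(schema = if (length(classes)) out_schema else schema,
       profiles = profiles)
}
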