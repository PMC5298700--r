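RULES_SCHEMA_VERSION <- 1L

#' Write / read situation rules as JSON
#'
#' Rules are persisted as a schema-versioned JSON document, the same shape a
#' definition UI would exchange with the service.
#'
#' @param rules A [situation_rules()] store.
#' @param path File path.
#' @return `path` invisibly (write); a [situation_rules()] store (read).
#' @export
write_rules_json <- function(rules, path) {
  stopifnot(inherits(rules, "situation_rules"))
  doc <- list(
    schema_version = RULES_SCHEMA_VERSION,
    situations = purrr::map(seq_len(nrow(rules)), function(i) {
      r <- rules[i, ]
      list(id = r$id, name = r$name,
           anchor = list(lat = r$lat, lon = r$lon),
           location_term = r$location_term,
           day_terms = as.list(r$day_terms[[1]]),
           time_terms = as.list(r$time_terms[[1]]),
           activities = as.list(r$activities[[1]]),
           availability = as.list(r$availability[[1]]))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rules_json
#' @export
read_rules_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version) ||
      doc$schema_version > RULES_SCHEMA_VERSION) {
    rlang::abort("Unsupported rules schema version.")
  }
  out <- situation_rules()
  for (s in doc$situations) {
    rule <- situation_rule(
      name = s$name, lat = s$anchor$lat, lon = s$anchor$lon,
      location_term = s$location_term,
      day_terms = unlist(s$day_terms),
      time_terms = unlist(s$time_terms),
      activities = unlist(s$activities),
      availability = unlist(s$availability),
      id = s$id)
    out <- add_situation(out, rule, override_doubt = TRUE)
  }
  out
}

#' Serialize the fuzzy vocabulary to JSON
#'
#' Writes every membership function (name, domain, cyclic flag, breakpoint
#' list) so other tools can reproduce the fuzzification exactly.
#'
#' @param vocabulary A [fuzzy_vocabulary()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_vocabulary_json <- function(vocabulary = fuzzy_vocabulary(), path) {
  doc <- list(
    schema_version = RULES_SCHEMA_VERSION,
    sets = purrr::map(vocabulary$sets, function(s) {
      list(name = s$name, domain = s$domain, cyclic = s$cyclic,
           breakpoints = purrr::map2(s$breakpoints$x, s$breakpoints$mu,
                                     ~ list(x = .x, mu = .y)))
    }),
    activity_classes = as.list(vocabulary$activity_classes)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export rules and sets as an FCL-style text block
#'
#' A write-only, simplified dialect of the Fuzzy Control Language
#' (IEC 61131-7) for interoperability with FCL-based fuzzy toolkits: one
#' FUZZIFY block per linguistic variable (terms as piecewise-linear point
#' lists) and one RULEBLOCK with a PROD-activated rule per situation.
#' Nuances the dialect cannot express (per-rule anchors, staleness decay)
#' are emitted as comments.
#'
#' @param rules A [situation_rules()] store.
#' @param path File path.
#' @param vocabulary A [fuzzy_vocabulary()].
#' @return `path`, invisibly.
#' @export
export_fcl <- function(rules, path, vocabulary = fuzzy_vocabulary()) {
  stopifnot(inherits(rules, "situation_rules"))
  term_line <- function(set) {
    pts <- paste(sprintf("(%g, %g)", set$breakpoints$x, set$breakpoints$mu),
                 collapse = " ")
    sprintf("    TERM %s := %s;", set$name, pts)
  }
  var_block <- function(var, terms) {
    c(sprintf("  FUZZIFY %s", var),
      purrr::map_chr(vocabulary$sets[terms], term_line),
      "  END_FUZZIFY")
  }
  rule_line <- function(i) {
    r <- rules[i, ]
    ors <- function(v, x) paste(sprintf("%s IS %s", v, x), collapse = " OR ")
    sprintf(
      "    RULE %d : IF (%s) AND (%s) AND (%s) AND (activity IS on_activity) THEN situation IS %s; // anchor (%.6f, %.6f); activities: %s",
      i,
      ors("location", r$location_term),
      ors("day_of_week", r$day_terms[[1]]),
      ors("time_of_day", r$time_terms[[1]]),
      r$id, r$lat, r$lon, paste(r$activities[[1]], collapse = ","))
  }
  lines <- c(
    "FUNCTION_BLOCK situation_inference",
    "  // simplified write-only FCL dialect; per-rule anchors and location-",
    "  // staleness confidence decay are outside IEC 61131-7 and shown as comments",
    var_block("location", vocabulary$location_terms),
    var_block("day_of_week", vocabulary$day_terms),
    var_block("time_of_day", vocabulary$time_terms),
    var_block("activity", vocabulary$activity_sets),
    "  RULEBLOCK situations",
    "    AND : PROD;",
    "    ACT : PROD;",
    purrr::map_chr(seq_len(nrow(rules)), rule_line),
    "  END_RULEBLOCK",
    "END_FUNCTION_BLOCK")
  writeLines(lines, path)
  invisible(path)
}
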