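# Declarative indicator engine: turns item-level responses into binary
# composite indicators with correct eligibility denominators.
#
# Each respondent x indicator cell takes one of four states:
#   "true" / "false"  -- eligible, indicator evaluated
#   "ineligible"      -- the eligibility (or applicability, or reporter)
#                        predicate fails; excluded from the denominator
#   "missing"         -- eligible but the responses needed to evaluate the
#                        rule are missing; excluded from numerator AND
#                        denominator
# Missingness policy: an any_of rule treats missing responses as
# non-qualifying unless every referenced item is missing (then the indicator
# is missing); an all_of (or composite) rule with any missing component is
# missing; single-item rules are missing when the item is missing. This is
# the conservative convention for act-list violence measures.

RULE_KINDS <- c("any_of", "all_of", "value_in", "negation", "composite")
IND_LEVELS <- c("outcome", "community", "relationship", "individual")

#' Parse indicator specifications from a YAML config
#'
#' The config has a single top-level key `indicators`, a list of entries with
#' fields `name`, `label` (optional), `level` (outcome / community /
#' relationship / individual), `reporter` (women / men / both), `eligibility`
#' (optional list of flags: `partnered_past_year`, `cohabiting`,
#' `witnessed_ipv`, `non_polygamous`, or `outcome` to condition on the
#' reporter's IPV outcome), `applicability` (optional list of yes/no items
#' that must be "yes"), and either `rule` or `rule_by_reporter`
#' (`women:`/`men:` sub-rules). A rule has `kind` (any_of, all_of, value_in,
#' negation, composite), `items` + `values` (the qualifying responses), or
#' `rules` for composites.
#'
#' The shipped default config (`system.file("extdata", "indicators.yaml",
#' package = "crtpathways")`) encodes the full measurement battery: both IPV
#' outcomes (the women's act list and the men's anonymous-card measure) and
#' 27 candidate mediators at the community, relationship and individual
#' levels, including the 12-scenario IPV-acceptability battery.
#'
#' @param path path to a YAML config file.
#' @return a list of `indicator_spec` objects.
#' @export
parse_indicator_specs <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$indicators) || !length(cfg$indicators))
    stop("config has no 'indicators' entry: ", path)
  dict <- item_dictionary()
  specs <- lapply(cfg$indicators, parse_one_spec, dict = dict)
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(names(specs)))
    stop("duplicate indicator names: ",
         paste(unique(names(specs)[duplicated(names(specs))]), collapse = ", "))
  specs
}

parse_one_spec <- function(x, dict) {
  if (is.null(x$name)) stop("indicator spec without a name")
  nm <- x$name
  if (is.null(x$level) || !x$level %in% IND_LEVELS)
    stop("indicator '", nm, "': level must be one of ",
         paste(IND_LEVELS, collapse = ", "))
  reporter <- x$reporter %||% "both"
  if (!reporter %in% c("women", "men", "both"))
    stop("indicator '", nm, "': reporter must be women, men or both")
  elig <- unlist(x$eligibility) %||% character()
  bad <- setdiff(elig, ELIGIBILITY_FLAGS)
  if (length(bad))
    stop("indicator '", nm, "': unknown eligibility flag(s): ",
         paste(bad, collapse = ", "))
  appl <- unlist(x$applicability) %||% character()
  bad <- setdiff(appl, names(dict))
  if (length(bad))
    stop("indicator '", nm, "': unknown applicability item(s): ",
         paste(bad, collapse = ", "))

  if (!is.null(x[["rule"]]) && !is.null(x[["rule_by_reporter"]]))
    stop("indicator '", nm, "': give either rule or rule_by_reporter")
  if (is.null(x[["rule"]]) && is.null(x[["rule_by_reporter"]]))
    stop("indicator '", nm, "': no rule given")
  rules <- if (!is.null(x[["rule"]])) {
    list(both = validate_rule(x[["rule"]], dict, nm))
  } else {
    if (!all(c("women", "men") %in% names(x[["rule_by_reporter"]])))
      stop("indicator '", nm, "': rule_by_reporter needs women and men entries")
    lapply(x[["rule_by_reporter"]], validate_rule, dict = dict, name = nm)
  }

  structure(list(name = nm, label = x$label %||% nm, level = x$level,
                 reporter = reporter, eligibility = elig,
                 applicability = appl, rules = rules),
            class = "indicator_spec")
}

validate_rule <- function(rule, dict, name, depth = 0L) {
  if (is.null(rule$kind) || !rule$kind %in% RULE_KINDS)
    stop("indicator '", name, "': rule kind must be one of ",
         paste(RULE_KINDS, collapse = ", "))
  if (rule$kind == "composite") {
    if (depth > 0L)
      stop("indicator '", name, "': composite rules cannot be nested")
    if (is.null(rule$rules) || length(rule$rules) < 1L)
      stop("indicator '", name, "': composite rule needs >= 1 sub-rules")
    rule$rules <- lapply(rule$rules, validate_rule, dict = dict, name = name,
                         depth = 1L)
    return(rule)
  }
  items <- unlist(rule$items)
  if (is.null(items) || length(items) < 1L)
    stop("indicator '", name, "': ", rule$kind, " rule needs >= 1 items")
  if (rule$kind %in% c("value_in", "negation") && length(items) != 1L)
    stop("indicator '", name, "': ", rule$kind, " rule takes exactly 1 item")
  bad <- setdiff(items, names(dict))
  if (length(bad))
    stop("indicator '", name, "': unknown item(s): ", paste(bad, collapse = ", "))
  values <- as.character(unlist(rule$values) %||% "yes")
  for (it in items) {
    badv <- setdiff(values, dict[[it]])
    if (length(badv))
      stop("indicator '", name, "': value(s) ", paste(badv, collapse = ", "),
           " not admissible for item ", it)
  }
  rule$items <- items
  rule$values <- values
  rule
}

# Evaluate one (non-composite) rule. Returns character "true"/"false"/"missing".
eval_rule <- function(rule, data) {
  n <- nrow(data)
  if (rule$kind == "composite") {
    parts <- vapply(rule$rules, eval_rule, character(n), data = data)
    if (n == 1L) parts <- matrix(parts, nrow = 1L)
    anyf <- apply(parts == "false", 1L, any)
    anym <- apply(parts == "missing", 1L, any)
    return(ifelse(anyf, "false", ifelse(anym, "missing", "true")))
  }
  cols <- lapply(rule$items, function(it) {
    if (!it %in% names(data))
      stop("data lacks item column '", it, "'")
    as.character(data[[it]])
  })
  qual <- vapply(cols, function(v) !is.na(v) & v %in% rule$values, logical(n))
  miss <- vapply(cols, is.na, logical(n))
  if (n == 1L) { qual <- matrix(qual, 1L); miss <- matrix(miss, 1L) }
  n_qual <- rowSums(qual)
  n_miss <- rowSums(miss)
  k <- length(cols)
  switch(rule$kind,
    any_of = ifelse(n_miss == k, "missing",
                    ifelse(n_qual >= 1L, "true", "false")),
    all_of = ifelse(n_miss > 0L, "missing",
                    ifelse(n_qual == k, "true", "false")),
    value_in = ifelse(n_miss == 1L, "missing",
                      ifelse(n_qual == 1L, "true", "false")),
    negation = ifelse(n_miss == 1L, "missing",
                      ifelse(n_qual == 1L, "false", "true"))
  )
}

#' Evaluate an indicator for every respondent in a roster
#'
#' @param spec an `indicator_spec`.
#' @param data a roster data frame (respondent records with item columns).
#' @param outcome_state optional character vector (one per row, states
#'   "true"/"false"/"ineligible"/"missing") of the reporter-matched IPV
#'   outcome, required when the spec's eligibility includes `outcome`.
#' @return character vector of states "true", "false", "ineligible",
#'   "missing".
#' @export
evaluate_indicator <- function(spec, data, outcome_state = NULL) {
  stopifnot(inherits(spec, "indicator_spec"))
  n <- nrow(data)
  out <- rep("ineligible", n)

  eligible <- rep(TRUE, n)
  if (spec$reporter == "women") eligible <- eligible & data$sex == "female"
  if (spec$reporter == "men") eligible <- eligible & data$sex == "male"
  for (flag in spec$eligibility) {
    if (flag == "outcome") {
      if (is.null(outcome_state))
        stop("indicator '", spec$name,
             "' conditions on the outcome; outcome_state required")
      eligible <- eligible & outcome_state == "true"
    } else if (flag == "non_polygamous") {
      eligible <- eligible & !is.na(data$polygamous) & data$polygamous == 0L
    } else {
      v <- data[[flag]]
      eligible <- eligible & !is.na(v) & v == 1L
    }
  }
  for (it in spec$applicability) {
    v <- as.character(data[[it]])
    eligible <- eligible & !is.na(v) & v == "yes"
  }
  if (!any(eligible)) return(out)

  sub <- data[eligible, , drop = FALSE]
  if (length(spec$rules) == 1L && names(spec$rules) == "both") {
    res <- eval_rule(spec$rules$both, sub)
  } else {
    res <- rep("missing", nrow(sub))
    fem <- sub$sex == "female"
    if (any(fem)) res[fem] <- eval_rule(spec$rules$women, sub[fem, , drop = FALSE])
    if (any(!fem)) res[!fem] <- eval_rule(spec$rules$men, sub[!fem, , drop = FALSE])
  }
  out[eligible] <- res
  out
}

#' Build the full respondent-by-indicator tri-state matrix
#'
#' Outcome-level indicators are evaluated first so that indicators whose
#' eligibility conditions on the outcome (e.g. disclosure among those
#' experiencing IPV) can resolve it; the reporter's outcome is the outcome
#' spec whose `reporter` matches.
#'
#' @param specs list of `indicator_spec` from [parse_indicator_specs()].
#' @param roster roster data frame; respondent ids must be unique.
#' @return an `indicator_matrix`: list with `values` (data frame of design
#'   columns plus one state column per indicator), `specs`, and
#'   `denominators` (per indicator x sex counts of each state, the
#'   denominator true+false, and the prevalence in percent).
#' @export
build_indicator_matrix <- function(specs, roster) {
  if (anyDuplicated(roster$respondent_id))
    stop("duplicate respondent ids in roster")
  design_cols <- intersect(
    c("respondent_id", "pair_id", "community_id", "ea_id", "arm", "sex"),
    names(roster))
  values <- roster[, design_cols, drop = FALSE]
  if (nrow(roster) == 0L) {
    denoms <- data.frame(indicator = character(), sex = character(),
                         n_true = integer(), n_false = integer(),
                         n_ineligible = integer(), n_missing = integer(),
                         denominator = integer(), prevalence = numeric())
    return(structure(list(values = values, specs = specs,
                          denominators = denoms),
                     class = "indicator_matrix"))
  }

  is_outcome <- vapply(specs, function(s) s$level == "outcome", logical(1))
  outcome_by_reporter <- list()
  for (s in specs[is_outcome]) {
    st <- evaluate_indicator(s, roster)
    values[[s$name]] <- st
    outcome_by_reporter[[s$reporter]] <- st
  }
  resolve_outcome <- function(spec) {
    # reporter-matched outcome state; "both" merges the two sex-specific ones
    if (spec$reporter %in% names(outcome_by_reporter))
      return(outcome_by_reporter[[spec$reporter]])
    sts <- outcome_by_reporter[c("women", "men")]
    sts <- sts[!vapply(sts, is.null, logical(1))]
    if (!length(sts)) stop("no outcome indicator available to condition on")
    merged <- rep("ineligible", nrow(roster))
    for (st in sts) merged[st != "ineligible"] <- st[st != "ineligible"]
    merged
  }
  for (s in specs[!is_outcome]) {
    os <- if ("outcome" %in% s$eligibility) resolve_outcome(s) else NULL
    values[[s$name]] <- evaluate_indicator(s, roster, outcome_state = os)
  }

  denoms <- do.call(rbind, lapply(specs, function(s) {
    st <- values[[s$name]]
    do.call(rbind, lapply(c("female", "male"), function(sx) {
      sti <- st[roster$sex == sx]
      nt <- sum(sti == "true"); nf <- sum(sti == "false")
      data.frame(indicator = s$name, level = s$level,
                 sex = sx, n_true = nt, n_false = nf,
                 n_ineligible = sum(sti == "ineligible"),
                 n_missing = sum(sti == "missing"),
                 denominator = nt + nf,
                 prevalence = prevalence_pct(nt, nt + nf))
    }))
  }))
  rownames(denoms) <- NULL
  structure(list(values = values, specs = specs, denominators = denoms),
            class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf("Indicator matrix: %d respondents x %d indicators\n",
              nrow(x$values), length(x$specs)))
  invisible(x)
}

#' Serialise / deserialise an indicator matrix
#'
#' States are coded 1 (true), 0 (false) and NA (ineligible or missing, both
#' excluded from denominators) alongside the design columns.
#'
#' @param im an `indicator_matrix`.
#' @param path CSV path.
#' @param specs the indicator specs used to rebuild denominators on read.
#' @return `read_indicator_matrix` returns an `indicator_matrix` whose
#'   NA cells carry the merged state "excluded".
#' @export
write_indicator_matrix <- function(im, path) {
  df <- im$values
  for (s in names(im$specs)) {
    st <- df[[s]]
    df[[s]] <- ifelse(st == "true", 1L, ifelse(st == "false", 0L, NA_integer_))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indicator_matrix
#' @export
read_indicator_matrix <- function(path, specs) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (s in names(specs)) {
    v <- df[[s]]
    df[[s]] <- ifelse(is.na(v), "excluded", ifelse(v == 1L, "true", "false"))
  }
  denoms <- do.call(rbind, lapply(specs, function(s) {
    st <- df[[s$name]]
    do.call(rbind, lapply(c("female", "male"), function(sx) {
      sti <- st[df$sex == sx]
      nt <- sum(sti == "true"); nf <- sum(sti == "false")
      data.frame(indicator = s$name, level = s$level, sex = sx,
                 n_true = nt, n_false = nf,
                 n_ineligible = NA_integer_, n_missing = NA_integer_,
                 denominator = nt + nf,
                 prevalence = prevalence_pct(nt, nt + nf))
    }))
  }))
  rownames(denoms) <- NULL
  structure(list(values = df, specs = specs, denominators = denoms),
            class = "indicator_matrix")
}

#' Path to the shipped default indicator configuration
#' @return file path of the packaged `indicators.yaml`.
#' @export
default_indicator_config <- function() {
  system.file("extdata", "indicators.yaml", package = "crtpathways",
              mustWork = TRUE)
}
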