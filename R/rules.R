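#' Build rule predicates for personalization
#'
#' Contraindication and outcome-relevance rules are boolean predicates over a
#' patient's profile attributes, restricted to a conjunction of disjunctions
#' (AND of ORs) of atomic comparisons. This shape is expressive enough for
#' clinical contraindication logic (for example, "severe renal impairment OR
#' lithium allergy excludes lithium") while remaining trivially auditable.
#'
#' `rule_atom()` builds one atomic comparison, `rule_clause()` ORs atoms
#' together, and `rule()` ANDs clauses. A bare atom passed to `rule()` is
#' wrapped in its own single-atom clause. A rule with zero clauses is
#' vacuously true.
#'
#' @param attribute Name of a patient attribute declared in the template's
#'   attribute dictionary.
#' @param op Comparison operator: one of `"="`, `"!="`, `"<"`, `"<="`, `">"`,
#'   `">="`, `"in"`.
#' @param value Constant to compare against (a vector for `"in"`).
#' @param ... Atoms (for `rule_clause()`) or clauses/atoms (for `rule()`).
#' @return `rule_atom()` an object of class `hopt_atom`; `rule_clause()` an
#'   object of class `hopt_clause`; `rule()` an object of class `hopt_rule`.
#' @examples
#' r <- rule(rule_clause(
#'   rule_atom("egfr_stage", "=", "severe"),
#'   rule_atom("lithium_allergy", "=", TRUE)
#' ))
#' evaluate_rule(r, list(egfr_stage = "moderate", lithium_allergy = TRUE))
#' @export
rule <- function(...) {
  clauses <- lapply(list(...), function(cl) {
    if (inherits(cl, "hopt_atom")) rule_clause(cl) else cl
  })
  if (!all(vapply(clauses, inherits, logical(1), "hopt_clause"))) {
    stop_hopt("rule() accepts only rule_clause() or rule_atom() objects", "healthopt_rule_error")
  }
  structure(list(clauses = clauses), class = "hopt_rule")
}

#' @rdname rule
#' @export
rule_clause <- function(...) {
  atoms <- list(...)
  if (!all(vapply(atoms, inherits, logical(1), "hopt_atom"))) {
    stop_hopt("rule_clause() accepts only rule_atom() objects", "healthopt_rule_error")
  }
  structure(list(atoms = atoms), class = "hopt_clause")
}

#' @rdname rule
#' @export
rule_atom <- function(attribute, op, value) {
  ops <- c("=", "!=", "<", "<=", ">", ">=", "in")
  if (!is.character(attribute) || length(attribute) != 1) {
    stop_hopt("attribute must be a single string", "healthopt_rule_error")
  }
  if (!op %in% ops) {
    stop_hopt(sprintf("unknown operator '%s'", op), "healthopt_rule_error")
  }
  structure(list(attribute = attribute, op = op, value = value), class = "hopt_atom")
}

rule_attributes <- function(rule) {
  if (is.null(rule)) return(character(0))
  unique(unlist(lapply(rule$clauses, function(cl) {
    vapply(cl$atoms, function(a) a$attribute, character(1))
  })))
}

eval_atom <- function(atom, attrs) {
  v <- attrs[[atom$attribute]]
  switch(atom$op,
    "="  = isTRUE(all.equal(v, atom$value)) || identical(v, atom$value) ||
           (is.numeric(v) && is.numeric(atom$value) && v == atom$value) ||
           (is.character(v) && is.character(atom$value) && v == atom$value),
    "!=" = !eval_atom(rule_atom(atom$attribute, "=", atom$value), attrs),
    "<"  = v < atom$value,
    "<=" = v <= atom$value,
    ">"  = v > atom$value,
    ">=" = v >= atom$value,
    "in" = v %in% atom$value
  )
}

#' Evaluate a rule predicate against a patient profile
#'
#' Applies AND-of-ORs semantics: the rule is true when every clause contains
#' at least one true atom. An empty rule (no clauses) is vacuously true.
#' A missing profile attribute is an error rather than "false": silently
#' retaining a contraindicated treatment is the dangerous failure mode.
#'
#' @param rule A [rule()] object, or `NULL` (treated as vacuously true).
#' @param profile A named list of attribute values, or a `patient_profile`.
#' @return A single logical value.
#' @export
evaluate_rule <- function(rule, profile) {
  if (is.null(rule)) return(TRUE)
  if (!inherits(rule, "hopt_rule")) {
    stop_hopt("rule must be a hopt_rule (see rule())", "healthopt_rule_error")
  }
  attrs <- if (inherits(profile, "patient_profile")) profile$attributes else profile
  needed <- rule_attributes(rule)
  absent <- needed[!needed %in% names(attrs)]
  if (length(absent) > 0) {
    stop_hopt(
      sprintf("missing attribute: %s", paste(absent, collapse = ", ")),
      "healthopt_missing_attribute"
    )
  }
  all(vapply(rule$clauses, function(cl) {
    any(vapply(cl$atoms, eval_atom, logical(1), attrs = attrs))
  }, logical(1)))
}

rule_to_list <- function(rule) {
  if (is.null(rule)) return(NULL)
  lapply(rule$clauses, function(cl) {
    lapply(cl$atoms, function(a) list(attribute = a$attribute, op = a$op, value = a$value))
  })
}

rule_from_list <- function(x) {
  if (is.null(x) || length(x) == 0) return(NULL)
  clauses <- lapply(x, function(cl) {
    do.call(rule_clause, lapply(cl, function(a) {
      val <- a$value
      if (is.list(val)) val <- unlist(val)
      rule_atom(a$attribute, a$op, val)
    }))
  })
  do.call(rule, clauses)
}

rule_text <- function(rule) {
  if (is.null(rule)) return("")
  paste(vapply(rule$clauses, function(cl) {
    paste0("(", paste(vapply(cl$atoms, function(a) {
      paste(a$attribute, a$op, paste(format(a$value), collapse = ","))
    }, character(1)), collapse = " OR "), ")")
  }, character(1)), collapse = " AND ")
}

#' @export
format.hopt_rule <- function(x, ...) rule_text(x)

#' @export
print.hopt_rule <- function(x, ...) {
  cat("<rule> ", rule_text(x), "\n", sep = "")
  invisible(x)
}
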