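## Deterministic dosing rules engine.  The clinical logic lives in a
## versioned declarative YAML table (inst/extdata/sup_rules.yaml); this file
## only interprets it: first matching rule in priority order wins, and the
## engine is total over the finite phenotype x drug x indication x flag
## space.

.PPI_DRUGS <- c("omeprazole", "esomeprazole", "lansoprazole", "pantoprazole",
                "rabeprazole", "dexlansoprazole")
.INDICATIONS <- c("SUP", "H_PYLORI_ERADICATION", "EROSIVE_ESOPHAGITIS")
.ACTIONS <- c("STANDARD_DOSE", "INCREASE", "REDUCE_CONSIDER", "SWITCH_AGENT",
              "NO_SPECIFIC_RECOMMENDATION")

#' Supported PPI drug tokens
#' @return Character vector.
#' @export
ppi_drugs <- function() .PPI_DRUGS

#' Supported indication tokens
#' @return Character vector: `SUP` (stress ulcer prophylaxis),
#'   `H_PYLORI_ERADICATION`, `EROSIVE_ESOPHAGITIS`.
#' @export
sup_indications <- function() .INDICATIONS

#' Standard SUP daily doses
#'
#' Reference daily doses for stress ulcer prophylaxis.  Dexlansoprazole has
#' no established standard SUP dose and carries `NA`.
#'
#' @return A data frame with columns `drug`, `dose_mg_per_day`,
#'   `duration_note`.
#' @export
#' @examples
#' standard_doses()
standard_doses <- function() {
  data.frame(
    drug = c("omeprazole", "lansoprazole", "pantoprazole", "esomeprazole",
             "rabeprazole", "dexlansoprazole"),
    dose_mg_per_day = c(20, 30, 20, 20, 20, NA),
    duration_note = c("4-8 weeks", "8 weeks", "4-8 weeks", "4-8 weeks",
                      "4-8 weeks", "no established SUP dose"),
    row.names = NULL
  )
}

## Rule-table cache (one load per session unless a path is given).
.rules_env <- new.env(parent = emptyenv())

#' Load the versioned dosing rule table
#'
#' @param path Optional path to an alternative YAML rule table; by default
#'   the table shipped with the package is used (and cached).
#' @return A list with elements `version`, `multiplier_scale`, and `rules`
#'   (the priority-ordered rule list).
#' @export
sup_rule_table <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.rules_env$default)) {
      default_path <- system.file("extdata", "sup_rules.yaml",
                                  package = "cyp2c19sup", mustWork = TRUE)
      .rules_env$default <- .load_rules(default_path)
    }
    return(.rules_env$default)
  }
  .load_rules(path)
}

.load_rules <- function(path) {
  tab <- yaml::read_yaml(path)
  if (is.null(tab$rules) || !length(tab$rules)) {
    stop("rule table has no rules: ", path, call. = FALSE)
  }
  ids <- vapply(tab$rules, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicated rule id in ", path, call. = FALSE)
  for (r in tab$rules) {
    if (!(r$action %in% .ACTIONS)) {
      stop("rule ", r$id, " has unknown action ", r$action, call. = FALSE)
    }
    if (is.null(r$rationale) || !nzchar(trimws(r$rationale))) {
      stop("rule ", r$id, " lacks a rationale", call. = FALSE)
    }
  }
  tab
}

#' Assemble a validated clinical context
#'
#' @param drug Prescribed PPI (see [ppi_drugs()]).
#' @param indication Treatment indication (see [sup_indications()]);
#'   default `"SUP"`.
#' @param chronic_over_12_weeks Is therapy planned/ongoing beyond 12 weeks?
#' @param h_pylori_positive Is the patient Helicobacter pylori positive?
#' @param ppi_hypersensitivity Known hypersensitivity to PPIs?
#' @param genotype_available Is a CYP2C19 genotype available for the
#'   patient?
#' @param interacting_cyp_drug Is the patient co-medicated with a drug with
#'   possible CYP3A4/CYP2C19 interaction?
#' @return A list of class `clinical_context`.
#' @export
#' @examples
#' clinical_context("omeprazole", "SUP")
clinical_context <- function(drug,
                             indication = "SUP",
                             chronic_over_12_weeks = FALSE,
                             h_pylori_positive = FALSE,
                             ppi_hypersensitivity = FALSE,
                             genotype_available = TRUE,
                             interacting_cyp_drug = FALSE) {
  if (length(drug) != 1L || !(drug %in% .PPI_DRUGS)) {
    stop("unknown drug '", paste(drug, collapse = ","), "'; expected one of: ",
         paste(.PPI_DRUGS, collapse = ", "), call. = FALSE)
  }
  if (length(indication) != 1L || !(indication %in% .INDICATIONS)) {
    stop("unknown indication '", paste(indication, collapse = ","),
         "'; expected one of: ", paste(.INDICATIONS, collapse = ", "),
         call. = FALSE)
  }
  flags <- list(chronic_over_12_weeks = chronic_over_12_weeks,
                h_pylori_positive = h_pylori_positive,
                ppi_hypersensitivity = ppi_hypersensitivity,
                genotype_available = genotype_available,
                interacting_cyp_drug = interacting_cyp_drug)
  for (nm in names(flags)) {
    if (!is.logical(flags[[nm]]) || length(flags[[nm]]) != 1L ||
        is.na(flags[[nm]])) {
      stop(nm, " must be TRUE or FALSE", call. = FALSE)
    }
  }
  structure(c(list(drug = drug, indication = indication), flags),
            class = "clinical_context")
}

.rule_matches <- function(rule, phenotype, ctx) {
  w <- rule$when %||% list()
  for (nm in names(w)) {
    want <- w[[nm]]
    have <- switch(nm,
                   phenotype = phenotype,
                   drug = ctx$drug,
                   indication = ctx$indication,
                   ctx[[nm]])
    if (is.null(have)) return(FALSE)
    if (is.logical(want)) {
      if (!identical(as.logical(have), want)) return(FALSE)
    } else if (!(have %in% unlist(want))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Recommend a PPI dosing action for a phenotype and clinical context
#'
#' Applies the versioned rule table in priority order and returns the first
#' matching rule as a recommendation.  The engine is total: every
#' combination of phenotype, drug, indication and flags yields exactly one
#' recommendation.  Hypersensitivity dominates all genotype logic; an
#' unavailable genotype, an UNKNOWN phenotype, or an interacting
#' co-medication each resolve to CYP2C19-independent therapy (rabeprazole
#' preferred at standard dose).
#'
#' @param phenotype A predictive phenotype label (see
#'   [phenotype_levels()]).
#' @param ctx A [clinical_context()].
#' @param rules A rule table from [sup_rule_table()].
#' @return An object of class `sup_recommendation`: a list with fields
#'   `rule_id`, `action`, `multiplier_low`, `multiplier_high`
#'   (dose factors relative to the standard SUP daily dose; `NA` for
#'   non-numeric actions), `preferred_agent` (`NA`, a drug token, or
#'   `"H2RA_or_GMP"`), `split_dose_allowed`, `rationale`, `provisional`
#'   (TRUE for the AM phenotype), plus the echoed `phenotype`, `drug`,
#'   `indication`.
#' @export
#' @examples
#' recommend("UM", clinical_context("omeprazole", "SUP"))
recommend <- function(phenotype, ctx, rules = sup_rule_table()) {
  if (length(phenotype) != 1L || !(phenotype %in% phenotype_levels())) {
    stop("unknown phenotype '", paste(phenotype, collapse = ","),
         "'; expected one of: ", paste(phenotype_levels(), collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(ctx, "clinical_context")) {
    stop("ctx must be built with clinical_context()", call. = FALSE)
  }
  for (rule in rules$rules) {
    if (.rule_matches(rule, phenotype, ctx)) {
      mult <- rule$multiplier
      lo <- if (is.null(mult)) NA_real_ else as.numeric(mult[[1]])
      hi <- if (is.null(mult)) NA_real_ else as.numeric(mult[[2]])
      return(structure(list(
        rule_id = rule$id,
        action = rule$action,
        multiplier_low = lo,
        multiplier_high = hi,
        preferred_agent = rule$preferred_agent %||% NA_character_,
        split_dose_allowed = isTRUE(rule$split_dose_allowed),
        rationale = trimws(rule$rationale),
        provisional = phenotype == "AM",
        phenotype = phenotype,
        drug = ctx$drug,
        indication = ctx$indication,
        rule_table_version = rules$version
      ), class = "sup_recommendation"))
    }
  }
  stop("no rule matched (rule table incomplete) for phenotype ", phenotype,
       ", drug ", ctx$drug, call. = FALSE)  # unreachable with shipped table
}

#' @export
print.sup_recommendation <- function(x, ...) {
  cat(sprintf("%s / %s / %s -> %s [%s]\n", x$phenotype, x$drug, x$indication,
              x$action, x$rule_id))
  if (!is.na(x$multiplier_low)) {
    cat(sprintf("  dose multiplier: %.2g-%.2g x standard%s\n",
                x$multiplier_low, x$multiplier_high,
                if (x$split_dose_allowed) " (may be split)" else ""))
  }
  if (!is.na(x$preferred_agent)) {
    cat("  preferred agent:", x$preferred_agent, "\n")
  }
  if (x$provisional) cat("  provisional (AM classification)\n")
  cat("  rationale:", x$rationale, "\n")
  invisible(x)
}

#' Convert a recommendation to an absolute daily dose range
#'
#' Multiplies the drug's standard SUP daily dose by the recommendation's
#' multiplier interval.  Dexlansoprazole (no printed standard SUP dose) and
#' non-numeric actions (agent switch, no specific recommendation) yield
#' `NA` with an explanatory note attribute.
#'
#' @param rec A `sup_recommendation`.
#' @param drug Drug token; defaults to the recommendation's drug.
#' @return Named numeric vector `c(low = , high = )` in mg/day, possibly
#'   `NA`, with attribute `"note"` when no numeric dose is available.
#' @export
#' @examples
#' absolute_dose(recommend("UM", clinical_context("omeprazole")))
absolute_dose <- function(rec, drug = rec$drug) {
  stopifnot(inherits(rec, "sup_recommendation"))
  std <- standard_doses()
  i <- match(drug, std$drug)
  if (is.na(i)) stop("unknown drug: ", drug, call. = FALSE)
  base <- std$dose_mg_per_day[i]
  if (is.na(base)) {
    out <- c(low = NA_real_, high = NA_real_)
    attr(out, "note") <- paste0(drug, " has no established standard SUP ",
                                "dose; recommendation is text-only")
    return(out)
  }
  if (is.na(rec$multiplier_low)) {
    out <- c(low = NA_real_, high = NA_real_)
    attr(out, "note") <- paste0("action ", rec$action,
                                " carries no numeric dose multiplier")
    return(out)
  }
  c(low = base * rec$multiplier_low, high = base * rec$multiplier_high)
}

#' Build a per-sample recommendation report for a called cohort
#'
#' One row per sample.  Uncallable samples (missing genotype slots) are
#' dosed under `genotype_available = FALSE` -- the CYP2C19-independent
#' fallback -- rather than dropped.  Every row carries the id of the rule
#' that fired.
#'
#' @param calls A `cyp2c19_calls` object from [call_cohort()].
#' @param ctx A [clinical_context()] providing the drug, indication, and
#'   flag defaults applied to every sample.
#' @param rules Rule table (see [sup_rule_table()]).
#' @return A data frame of class `sup_report` with one row per sample and
#'   columns `sample_id`, `haplogenotype`, `phenotype`, `rule_id`, `action`,
#'   `multiplier_low`, `multiplier_high`, `dose_low_mg`, `dose_high_mg`,
#'   `preferred_agent`, `split_dose_allowed`, `provisional`, `rationale`.
#'   The clinical context and rule-table version are stored as attributes.
#' @export
recommendation_report <- function(calls, ctx, rules = sup_rule_table()) {
  stopifnot(inherits(calls, "cyp2c19_calls"))
  if (!inherits(ctx, "clinical_context")) {
    stop("ctx must be built with clinical_context()", call. = FALSE)
  }
  n_call <- nrow(calls$calls)
  n_un <- nrow(calls$uncallable)
  rows <- rbind(
    data.frame(sample_id = calls$calls$sample_id,
               haplogenotype = calls$calls$haplogenotype,
               phenotype = calls$calls$phenotype,
               callable = rep(TRUE, n_call), row.names = NULL),
    data.frame(sample_id = calls$uncallable$sample_id,
               haplogenotype = rep(NA_character_, n_un),
               phenotype = rep(NA_character_, n_un),
               callable = rep(FALSE, n_un), row.names = NULL)
  )
  rec_one <- function(i) {
    if (rows$callable[i]) {
      recommend(rows$phenotype[i], ctx, rules)
    } else {
      ctx_nogeno <- ctx
      ctx_nogeno$genotype_available <- FALSE
      recommend("UNKNOWN", ctx_nogeno, rules)
    }
  }
  recs <- lapply(seq_len(nrow(rows)), rec_one)
  get_chr <- function(f) vapply(recs, function(r) as.character(r[[f]]), "")
  get_num <- function(f) vapply(recs, function(r) as.numeric(r[[f]]), 0)
  get_lgl <- function(f) vapply(recs, function(r) as.logical(r[[f]]), TRUE)
  doses <- lapply(recs, absolute_dose)
  report <- data.frame(
    sample_id = rows$sample_id,
    haplogenotype = rows$haplogenotype,
    phenotype = rows$phenotype,
    rule_id = if (nrow(rows)) get_chr("rule_id") else character(0),
    action = if (nrow(rows)) get_chr("action") else character(0),
    multiplier_low = if (nrow(rows)) get_num("multiplier_low") else numeric(0),
    multiplier_high = if (nrow(rows)) get_num("multiplier_high") else numeric(0),
    dose_low_mg = vapply(doses, `[[`, 0, 1L),
    dose_high_mg = vapply(doses, `[[`, 0, 2L),
    preferred_agent = if (nrow(rows)) get_chr("preferred_agent") else character(0),
    split_dose_allowed = if (nrow(rows)) get_lgl("split_dose_allowed") else logical(0),
    provisional = if (nrow(rows)) get_lgl("provisional") else logical(0),
    rationale = if (nrow(rows)) get_chr("rationale") else character(0),
    row.names = NULL
  )
  attr(report, "context") <- ctx
  attr(report, "rule_table_version") <- rules$version
  class(report) <- c("sup_report", "data.frame")
  report
}

#' Write a recommendation report as JSON
#'
#' Machine-readable rendering: a top-level object with the tool and
#' rule-table versions, the clinical context, and one record per sample.
#'
#' @param report A `sup_report` from [recommendation_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recommendation_json <- function(report, path) {
  stopifnot(inherits(report, "sup_report"))
  ctx <- attr(report, "context")
  payload <- list(
    tool = "cyp2c19sup",
    tool_version = as.character(utils::packageVersion("cyp2c19sup")),
    rule_table_version = attr(report, "rule_table_version"),
    context = unclass(ctx),
    recommendations = as.data.frame(report)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}

#' @export
format.sup_report <- function(x, ...) {
  ctx <- attr(x, "context")
  head <- sprintf("PPI recommendation report | drug=%s indication=%s | rules v%s",
                  ctx$drug, ctx$indication, attr(x, "rule_table_version"))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    dose <- if (is.na(x$dose_low_mg[i])) "" else
      sprintf(" (%g-%g mg/day)", x$dose_low_mg[i], x$dose_high_mg[i])
    sprintf("%s: %s -> %s%s [%s]%s", x$sample_id[i],
            ifelse(is.na(x$phenotype[i]), "uncalled", x$phenotype[i]),
            x$action[i], dose, x$rule_id[i],
            ifelse(x$provisional[i], " (provisional)", ""))
  }, character(1))
  paste(c(head, lines), collapse = "\n")
}

#' @export
print.sup_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
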