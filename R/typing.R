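# Rule-based atom typing. A rule matches on the element, optionally on the
# exact multiset of bonded neighbour elements, and optionally on the already
# assigned type label of a bonded neighbour (so hydrogens can be typed after
# their heavy atom). Rules are ordered; the first match wins.

#' Atom-typing rule set
#'
#' @param label Type label the rule emits.
#' @param element Element symbol the rule applies to.
#' @param neighbors Exact multiset of bonded neighbour elements as a
#'   comma-separated string (e.g. `"H,O,O"`), or `NA` to accept any
#'   environment.
#' @param attached_label Type label one bonded neighbour must already carry,
#'   or `NA`. Rules with this field fire on a later pass, once the neighbour
#'   is typed.
#' @return A tibble of class `fgc_typing` with one rule per row.
#' @export
typing_rules <- function(label, element, neighbors = NA_character_,
                         attached_label = NA_character_) {
  rules <- tibble::tibble(
    label = as.character(label),
    element = as.character(element),
    neighbors = rep_len(as.character(neighbors), length(label)),
    attached_label = rep_len(as.character(attached_label), length(label))
  )
  class(rules) <- c("fgc_typing", class(rules))
  rules
}

#' Built-in typing rules for methane, formic acid and ammonia
#'
#' Formic acid receives five distinct labels — carboxyl carbon `C`, carbonyl
#' oxygen `O`, hydroxyl oxygen `OH`, hydroxyl hydrogen `HO` and the
#' carbon-bound hydrogen `HCO` — so a formic acid homodimer exhibits 15
#' distinct pair types. Ammonia receives `N`/`HN` and methane `CM`/`HM`.
#'
#' @return An `fgc_typing` rule table.
#' @export
default_typing <- function() {
  typing_rules(
    label          = c("CM",      "C",     "OH",  "O", "N",     "HO", "HM", "HCO", "HN"),
    element        = c("C",       "C",     "O",   "O", "N",     "H",  "H",  "H",   "H"),
    neighbors      = c("H,H,H,H", "H,O,O", "C,H", "C", "H,H,H", NA,   NA,   NA,    NA),
    attached_label = c(NA,        NA,      NA,    NA,  NA,      "OH", "CM", "C",   "N")
  )
}

#' Read typing rules from a CSV file
#'
#' Columns: `label`, `element`, and optionally `neighbors`, `attached_label`
#' (see [typing_rules()]).
#'
#' @param path CSV path.
#' @return An `fgc_typing` rule table.
#' @export
read_typing <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("label", "element") %in% names(df))) {
    abort("typing file must have columns 'label' and 'element'")
  }
  typing_rules(df$label, df$element,
               df$neighbors %||% NA_character_,
               df$attached_label %||% NA_character_)
}

neighbor_key <- function(elems) paste(sort(elems), collapse = ",")

#' Assign atom types by rule
#'
#' Connectivity is inferred from the covalent-radius distance criterion, then
#' the ordered rules are applied repeatedly until every atom is labelled
#' (rules conditioned on a neighbour's label fire once that label exists).
#'
#' @param mol A molecule.
#' @param typing An `fgc_typing` rule table; defaults to [default_typing()].
#' @return The molecule with its `type` column filled in.
#' @export
assign_types <- function(mol, typing = default_typing()) {
  adj <- connectivity(mol)
  n <- nrow(mol)
  types <- rep(NA_character_, n)
  nb_keys <- vapply(seq_len(n), function(i) neighbor_key(mol$element[adj[i, ]]), "")
  repeat {
    progressed <- FALSE
    for (i in which(is.na(types))) {
      for (k in seq_len(nrow(typing))) {
        rule <- typing[k, ]
        if (rule$element != mol$element[i]) next
        if (!is.na(rule$neighbors) &&
            neighbor_key(strsplit(rule$neighbors, ",")[[1]]) != nb_keys[i]) next
        if (!is.na(rule$attached_label) &&
            !any(types[adj[i, ]] == rule$attached_label, na.rm = TRUE)) next
        types[i] <- rule$label
        progressed <- TRUE
        break
      }
    }
    if (!anyNA(types) || !progressed) break
  }
  if (anyNA(types)) {
    bad <- which(is.na(types))[1]
    abort(sprintf("no typing rule matches atom %d (element '%s')", bad, mol$element[bad]))
  }
  mol$type <- types
  mol
}
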