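#' Residue selections
#'
#' A `residue_selection` names an ordered set of `(chain, residue)` members
#' plus an atom filter; [resolve_selection()] turns it into atom indices
#' against a concrete topology. Selections are how analyses name the NTD,
#' the N+M region or the CTD of each protomer.
#'
#' @param members A data frame with columns `chain_id` and `residue_id`, or a
#'   character vector of range strings like `"A:474-487"` / `"B:12"`
#'   (1-based, inclusive).
#' @param atom_filter One of `"all"`, `"backbone"` (N, CA, C, O),
#'   `"c_alpha"` (CA only), `"heavy"` (non-hydrogen).
#'
#' @return A `residue_selection` object.
#' @examples
#' residue_selection(c("A:1-10", "B:1-10"), atom_filter = "c_alpha")
#' @export
residue_selection <- function(members, atom_filter = c("all", "backbone", "c_alpha", "heavy")) {
  atom_filter <- match.arg(atom_filter)
  if (length(members) == 0L || (is.data.frame(members) && nrow(members) == 0L)) {
    stop_allodyn("selection has no members", class = "allodyn_selection_error")
  }
  if (is.character(members)) members <- parse_selection_strings(members)
  members <- as_tibble(members)[, c("chain_id", "residue_id")]
  members$chain_id <- as.character(members$chain_id)
  members$residue_id <- as.integer(members$residue_id)
  if (nrow(members) == 0L) {
    stop_allodyn("selection has no members", class = "allodyn_selection_error")
  }
  if (anyDuplicated(paste(members$chain_id, members$residue_id))) {
    stop_allodyn("selection members must be unique", class = "allodyn_selection_error")
  }
  structure(list(members = members, atom_filter = atom_filter),
            class = "residue_selection")
}

parse_selection_strings <- function(x) {
  parts <- lapply(x, function(s) {
    m <- regmatches(s, regexec("^\\s*([A-Za-z0-9]+)\\s*:\\s*(-?[0-9]+)(?:\\s*-\\s*(-?[0-9]+))?\\s*$", s))[[1]]
    if (length(m) == 0L) {
      stop_allodyn(sprintf("cannot parse selection string '%s' (expected 'CHAIN:FROM-TO')", s),
                   class = "allodyn_selection_error")
    }
    from <- as.integer(m[3])
    to <- if (m[4] == "") from else as.integer(m[4])
    tibble(chain_id = m[2], residue_id = seq(from, to))
  })
  dplyr::bind_rows(parts)
}

#' @export
print.residue_selection <- function(x, ...) {
  cat(sprintf("<residue_selection> %d residues, atom_filter = %s\n",
              nrow(x$members), x$atom_filter))
  invisible(x)
}

#' @export
format.residue_selection <- function(x, ...) {
  sprintf("%d residues/%s", nrow(x$members), x$atom_filter)
}

selections_compatible <- function(a, b) {
  identical(a$atom_filter, b$atom_filter) &&
    nrow(a$members) == nrow(b$members) &&
    all(a$members$chain_id == b$members$chain_id) &&
    all(a$members$residue_id == b$members$residue_id)
}

#' Resolve a selection to atom indices
#'
#' @param selection A [residue_selection()].
#' @param ensemble A [trajectory_ensemble()] (or its topology tibble).
#' @return Integer atom indices in topology order, with the atom filter
#'   applied.
#' @export
resolve_selection <- function(selection, ensemble) {
  top <- if (inherits(ensemble, "trajectory_ensemble")) ensemble$topology else as_tibble(ensemble)
  top_key <- paste(top$chain_id, top$residue_id)
  mem_key <- paste(selection$members$chain_id, selection$members$residue_id)
  missing <- setdiff(mem_key, top_key)
  if (length(missing) > 0L) {
    stop_allodyn(
      sprintf("selection member(s) not in topology: %s",
              paste(gsub(" ", ":", missing), collapse = ", ")),
      class = "allodyn_selection_error"
    )
  }
  idx <- which(top_key %in% mem_key)
  idx <- switch(selection$atom_filter,
    all = idx,
    backbone = idx[top$is_backbone[idx]],
    c_alpha = idx[top$atom_name[idx] == "CA"],
    heavy = idx[top$is_heavy[idx]]
  )
  if (length(idx) == 0L) {
    stop_allodyn("selection resolves to zero atoms after the atom filter",
                 class = "allodyn_selection_error")
  }
  idx
}

#' Select every residue of one chain
#'
#' Convenience constructor for whole-protomer selections.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param chain_id Chain label.
#' @inheritParams residue_selection
#' @return A [residue_selection()].
#' @export
chain_selection <- function(ensemble, chain_id, atom_filter = "c_alpha") {
  top <- ensemble$topology
  rows <- top[top$chain_id == chain_id, c("chain_id", "residue_id")]
  if (nrow(rows) == 0L) {
    stop_allodyn(sprintf("chain '%s' not present in topology", chain_id),
                 class = "allodyn_selection_error")
  }
  residue_selection(unique(rows), atom_filter = atom_filter)
}
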