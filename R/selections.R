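#' Select atoms with a small expression language
#'
#' Supported primaries: `name <v> [<v> ...]`, `resname <v> ...`,
#' `resid <i>` or `resid <a>:<b>`, `group <g>`, `element <v>`, `all`,
#' combined with `and`, `or`, `not` and parentheses. Matching is exact and
#' case-sensitive for names, numeric for residue ids.
#'
#' @param system a `MolecularSystem`.
#' @param expr selection string, e.g. `"group ligand and name C9"`.
#' @return sorted integer vector of atom indices (possibly empty).
#' @examples
#' \dontrun{
#' select_atoms(sys, "name P")
#' select_atoms(sys, "group protein and not element H")
#' }
#' @export
select_atoms <- function(system, expr) {
  toks <- sel_tokenize(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  idx <- sel_parse_or(st, system)
  if (st$pos <= length(st$toks))
    stop("selection syntax error at token ", st$pos, ": unexpected '",
         st$toks[st$pos], "'")
  sort(unique(idx))
}

sel_tokenize <- function(expr) {
  spaced <- gsub("\\)", " ) ", gsub("\\(", " ( ", expr))
  toks <- strsplit(trimws(spaced), "\\s+")[[1]]
  toks[nzchar(toks)]
}

sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

sel_next <- function(st) {
  tok <- sel_peek(st)
  st$pos <- st$pos + 1L
  tok
}

sel_parse_or <- function(st, system) {
  idx <- sel_parse_and(st, system)
  while (identical(sel_peek(st), "or")) {
    sel_next(st)
    idx <- union(idx, sel_parse_and(st, system))
  }
  idx
}

sel_parse_and <- function(st, system) {
  idx <- sel_parse_factor(st, system)
  while (identical(sel_peek(st), "and")) {
    sel_next(st)
    idx <- intersect(idx, sel_parse_factor(st, system))
  }
  idx
}

sel_keywords <- c("name", "resname", "resid", "group", "element", "all",
                  "and", "or", "not", "(", ")")

sel_parse_factor <- function(st, system) {
  tok <- sel_peek(st)
  if (is.na(tok))
    stop("selection syntax error at token ", st$pos, ": unexpected end of expression")
  if (tok == "not") {
    sel_next(st)
    return(setdiff(seq_len(n_atoms(system)), sel_parse_factor(st, system)))
  }
  if (tok == "(") {
    sel_next(st)
    idx <- sel_parse_or(st, system)
    if (!identical(sel_peek(st), ")"))
      stop("selection syntax error at token ", st$pos, ": expected ')'")
    sel_next(st)
    return(idx)
  }
  sel_parse_primary(st, system)
}

sel_values <- function(st) {
  vals <- character(0)
  repeat {
    tok <- sel_peek(st)
    if (is.na(tok) || tok %in% sel_keywords) break
    vals <- c(vals, sel_next(st))
  }
  if (length(vals) == 0L)
    stop("selection syntax error at token ", st$pos, ": expected a value")
  vals
}

sel_parse_primary <- function(st, system) {
  at <- system$atoms
  tok <- sel_next(st)
  switch(tok,
    all = seq_len(nrow(at)),
    name = which(at$name %in% sel_values(st)),
    resname = which(at$resname %in% sel_values(st)),
    element = which(at$element %in% sel_values(st)),
    resid = {
      vals <- sel_values(st)
      ids <- integer(0)
      for (v in vals) {
        if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
          ab <- as.integer(strsplit(v, ":")[[1]])
          ids <- c(ids, seq(ab[1], ab[2]))
        } else if (grepl("^-?[0-9]+$", v)) {
          ids <- c(ids, as.integer(v))
        } else {
          stop("selection syntax error at token ", st$pos - 1L,
               ": '", v, "' is not a residue id or range")
        }
      }
      which(at$resid %in% ids)
    },
    group = {
      g <- sel_values(st)
      unknown <- setdiff(g, names(system$groups))
      if (length(unknown))
        stop("unknown group(s) in selection: ", paste(unknown, collapse = ", "))
      sort(unique(unlist(system$groups[g])))
    },
    stop("selection syntax error at token ", st$pos - 1L,
         ": unknown token '", tok, "'")
  )
}

# resolve either a selection string or an explicit index vector
resolve_selection <- function(system, sel) {
  if (is.character(sel) && length(sel) == 1L) return(select_atoms(system, sel))
  idx <- as.integer(sel)
  if (length(idx) && (any(idx < 1L) || any(idx > n_atoms(system))))
    stop("atom indices out of range")
  idx
}
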