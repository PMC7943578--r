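#' Select atoms with a small predicate language
#'
#' The predicate is a string combining primitive terms with `and`, `or`,
#' `not` and parentheses:
#'
#' * `all` / `none`
#' * `backbone` — atoms named N, CA, C, O
#' * `chain A B ...`
#' * `name CA CB ...`
#' * `resname ALA GLY ...`
#' * `resno 13` or `resno 3:26` (ranges inclusive)
#' * `occ > 0` (also `>=`, `<`, `<=`, `==` with a numeric literal) — e.g.
#'   `occ > 0` excludes zero-occupancy crystallographic atoms
#'
#' Examples: `"backbone"`, `"name CB and resname ALA"`,
#' `"chain A and resno 3:26 and occ > 0"`, `"not chain A"`.
#'
#' Selection preserves atom order and is idempotent; an empty result is
#' allowed and returned as a zero-atom structure.
#'
#' @param x a `cc_structure` or `cc_ensemble`.
#' @param predicate selection string.
#' @return Object of the same class as `x`, restricted to matching atoms.
#' @export
select_atoms <- function(x, predicate) {
  if (inherits(x, "cc_ensemble")) {
    mask <- selection_mask(x$atom, predicate)
    return(cc_ensemble(x$atom[mask, , drop = FALSE],
                       x$coords[mask, , , drop = FALSE], x$provenance))
  }
  if (!inherits(x, "cc_structure")) stop("x must be a cc_structure or cc_ensemble")
  mask <- selection_mask(x$atom, predicate)
  s <- x
  s$atom <- x$atom[mask, , drop = FALSE]
  s$xyz <- x$xyz[mask, , drop = FALSE]
  s
}

#' Logical mask for a selection predicate
#'
#' @param atom atom table of a structure/ensemble.
#' @param predicate selection string (see [select_atoms()]).
#' @return Logical vector with one entry per atom.
#' @export
selection_mask <- function(atom, predicate) {
  tokens <- tokenize_selection(predicate)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$pos <- 1L
  mask <- parse_or(st, atom)
  if (st$pos <= length(st$tokens)) {
    stop("selection error: unexpected token '", st$tokens[st$pos],
         "' in \"", predicate, "\"")
  }
  mask
}

tokenize_selection <- function(predicate) {
  if (!is.character(predicate) || length(predicate) != 1L || !nzchar(trimws(predicate))) {
    stop("selection error: predicate must be a non-empty string")
  }
  s <- gsub("([()])", " \\1 ", predicate)
  s <- gsub("(>=|<=|==|>|<)", " \\1 ", s)
  tokens <- strsplit(trimws(s), "\\s+")[[1]]
  tokens
}

peek <- function(st) if (st$pos <= length(st$tokens)) st$tokens[st$pos] else NA_character_
advance <- function(st) { t <- peek(st); st$pos <- st$pos + 1L; t }

parse_or <- function(st, atom) {
  m <- parse_and(st, atom)
  while (!is.na(peek(st)) && tolower(peek(st)) == "or") {
    advance(st)
    m <- m | parse_and(st, atom)
  }
  m
}

parse_and <- function(st, atom) {
  m <- parse_unary(st, atom)
  while (!is.na(peek(st)) && tolower(peek(st)) == "and") {
    advance(st)
    m <- m & parse_unary(st, atom)
  }
  m
}

parse_unary <- function(st, atom) {
  t <- peek(st)
  if (is.na(t)) stop("selection error: unexpected end of predicate")
  if (tolower(t) == "not") {
    advance(st)
    return(!parse_unary(st, atom))
  }
  if (t == "(") {
    advance(st)
    m <- parse_or(st, atom)
    if (is.na(peek(st)) || peek(st) != ")") stop("selection error: missing ')'")
    advance(st)
    return(m)
  }
  parse_term(st, atom)
}

is_term_end <- function(t) {
  is.na(t) || tolower(t) %in% c("and", "or", "not") || t %in% c("(", ")")
}

collect_args <- function(st) {
  args <- character(0)
  while (!is_term_end(peek(st))) args <- c(args, advance(st))
  if (length(args) == 0L) stop("selection error: keyword needs arguments")
  args
}

parse_term <- function(st, atom) {
  kw <- tolower(advance(st))
  switch(kw,
    all = rep(TRUE, nrow(atom)),
    none = rep(FALSE, nrow(atom)),
    backbone = atom$name %in% BACKBONE_ATOMS,
    chain = atom$chain %in% collect_args(st),
    name = atom$name %in% toupper(collect_args(st)),
    resname = atom$resname %in% toupper(collect_args(st)),
    resno = {
      args <- collect_args(st)
      nums <- unlist(lapply(args, function(a) {
        if (grepl("^-?[0-9]+:-?[0-9]+$", a)) {
          rng <- as.integer(strsplit(a, ":")[[1]])
          seq(rng[1], rng[2])
        } else if (grepl("^-?[0-9]+$", a)) {
          as.integer(a)
        } else {
          stop("selection error: bad residue number '", a, "'")
        }
      }))
      atom$resno %in% nums
    },
    occ = {
      op <- advance(st)
      val <- suppressWarnings(as.numeric(advance(st)))
      if (!op %in% c(">", ">=", "<", "<=", "==") || is.na(val)) {
        stop("selection error: occ needs a comparison like 'occ > 0'")
      }
      do.call(op, list(atom$occ, val))
    },
    stop("selection error: unknown keyword '", kw, "'")
  )
}
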