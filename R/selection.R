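#' Select atoms by a query expression
#'
#' Supports a small, deterministic selection grammar over the atom table:
#' `resname X`, `name Y`, `resid a:b` (or a single `resid a`), combined with
#' `and`, `or`, `not`, and parentheses (`not` binds tightest, then `and`,
#' then `or`). Matching is exact on trimmed names. The result is a sorted set
#' of unique 1-based atom indices; an empty selection is allowed and raises a
#' warning. Commutative operators are order-invariant.
#'
#' @param traj a [trajectory()].
#' @param query selection string, e.g. `"resname CHL and name O3"`.
#' @return object of class `"atom_selection"`: list with sorted integer
#'   `indices` and the original `query`.
#' @examples
#' at <- data.frame(resid = 1:3, resname = c("DOPC", "CHL", "CHL"),
#'                  name = c("P", "O3", "C1"))
#' tr <- trajectory(at, array(0, c(3, 3, 1)), c(5, 5, 5))
#' select_atoms(tr, "resname CHL and name O3")$indices
#' @export
select_atoms <- function(traj, query) {
  stopifnot(inherits(traj, "trajectory"), is.character(query),
            length(query) == 1L)
  toks <- strsplit(gsub("([()])", " \\1 ", query), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("empty selection query", call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  peek <- function() if (st$pos <= length(st$toks)) st$toks[st$pos] else NA
  advance <- function() { t <- peek(); st$pos <- st$pos + 1L; t }
  atoms <- traj$atoms

  parse_primary <- function() {
    t <- advance()
    if (is.na(t)) stop("selection parse error: unexpected end of query",
                       call. = FALSE)
    if (t == "(") {
      v <- parse_or()
      if (!identical(advance(), ")"))
        stop("selection parse error: missing ')'", call. = FALSE)
      return(v)
    }
    key <- tolower(t)
    if (!key %in% c("resname", "name", "resid"))
      stop("selection parse error: unexpected token '", t, "'", call. = FALSE)
    val <- advance()
    if (is.na(val))
      stop("selection parse error: '", key, "' needs a value", call. = FALSE)
    if (key == "resname") return(atoms$resname == val)
    if (key == "name") return(atoms$name == val)
    rng <- suppressWarnings(as.integer(strsplit(val, ":", fixed = TRUE)[[1]]))
    if (anyNA(rng) || !length(rng) %in% 1:2)
      stop("selection parse error: bad resid range '", val, "'",
           call. = FALSE)
    if (length(rng) == 1L) rng <- c(rng, rng)
    atoms$resid >= rng[1] & atoms$resid <= rng[2]
  }
  parse_not <- function() {
    if (!is.na(peek()) && tolower(peek()) == "not") { advance(); return(!parse_not()) }
    parse_primary()
  }
  parse_and <- function() {
    v <- parse_not()
    while (!is.na(peek()) && tolower(peek()) == "and") { advance(); v <- v & parse_not() }
    v
  }
  parse_or <- function() {
    v <- parse_and()
    while (!is.na(peek()) && tolower(peek()) == "or") { advance(); v <- v | parse_and() }
    v
  }
  mask <- parse_or()
  if (st$pos <= length(st$toks))
    stop("selection parse error: trailing tokens from '", peek(), "'",
         call. = FALSE)
  idx <- which(mask)
  if (!length(idx)) warning("selection '", query, "' matched no atoms",
                            call. = FALSE)
  structure(list(indices = idx, query = query), class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("atom_selection: %d atom(s) for query \"%s\"\n",
              length(x$indices), x$query))
  invisible(x)
}

# Resolve a selection-like argument to integer indices.
as_indices <- function(sel) {
  if (inherits(sel, "atom_selection")) return(sel$indices)
  if (is.numeric(sel)) return(as.integer(sel))
  stop("expected an atom_selection or an integer index vector", call. = FALSE)
}
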