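# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

#' Deterministic chromosome ordering
#'
#' Placed chromosomes come first, natural-sorted (numeric names by value,
#' e.g. `2` before `10`, then alphabetic names such as `X` or `LGf`);
#' unplaced scaffolds follow in lexical order. The ordering is total, so
#' any downstream sort of a gene table is reproducible.
#'
#' @param chromosome Character vector of chromosome/scaffold names.
#' @param placed Logical vector, same length: `FALSE` marks unplaced contigs.
#' @return Character vector of unique chromosome names in canonical order.
#' @export
chromosome_levels <- function(chromosome, placed = rep(TRUE, length(chromosome))) {
  stopifnot(length(chromosome) == length(placed))
  keep <- !is.na(chromosome)
  chromosome <- chromosome[keep]
  placed <- placed[keep]
  if (length(chromosome) == 0L) return(character())
  # a name is "placed" if any record on it is placed
  tab <- tapply(placed, chromosome, any)
  nm <- names(tab)
  is_placed <- as.logical(tab)
  stripped <- sub("^chr", "", nm)
  num <- suppressWarnings(as.numeric(stripped))
  p_num <- nm[is_placed & !is.na(num)]
  p_alp <- nm[is_placed & is.na(num)]
  p_num <- p_num[order(num[match(p_num, nm)])]
  p_alp <- p_alp[order(p_alp, method = "radix")]
  u <- nm[!is_placed]
  u <- u[order(u, method = "radix")]
  c(p_num, p_alp, u)
}

# stop with a classed synloss error
abort_synloss <- function(msg, class = "synloss_error", ...) {
  rlang::abort(msg, class = c(class, "synloss_error"), ...)
}

# integer-safe run id over a logical vector: consecutive TRUEs share an id,
# FALSE positions get NA
run_ids <- function(flag) {
  r <- rle(flag)
  id <- rep.int(cumsum(r$values), r$lengths)
  id[!flag] <- NA_integer_
  id
}

# column name for a species-specific field
sp_col <- function(species, field) paste(species, field, sep = "_")

ORTHOLOGY_CLASSES <- c("one2one", "apparent_one2one", "one2many", "many2many", "none")

# classes treated as usable 1-to-1 links for screening (the apparent class
# is pooled with strict 1-to-1)
ONE2ONE_CLASSES <- c("one2one", "apparent_one2one")
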