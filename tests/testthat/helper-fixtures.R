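# In-code fixtures: small ortholog tables built deterministically.

# sequential gene layout: one row per gene, coordinates laid along each
# chromosome with fixed gene length and gap
gene_layout <- function(n, chr = rep("1", n), gene_len = 20000, gap = 10000,
                        strand = rep("+", n), ids = sprintf("g%03d", seq_len(n))) {
  start <- numeric(n)
  end <- numeric(n)
  len <- rep_len(gene_len, n)
  for (ch in unique(chr)) {
    sel <- which(chr == ch)
    st <- cumsum(c(1, len[sel][-length(sel)] + gap))
    start[sel] <- st
    end[sel] <- st + len[sel] - 1
  }
  tibble::tibble(gene_id = ids, chr = chr, start = start, end = end,
                 strand = strand, placed = TRUE)
}

# assemble an ortholog_tbl from per-species layouts; focal genes missing
# from `focal` get NA entries and class "none"
make_tbl <- function(ref1, ref2 = ref1, focal = ref1,
                     species = c("lizard", "human", "chicken"),
                     classes = NULL) {
  stopifnot(setequal(ref1$gene_id, ref2$gene_id))
  n <- nrow(ref1)
  dat <- tibble::tibble(gene_id = ref1$gene_id)
  add_species <- function(dat, s, lay, prefix_ids = TRUE) {
    m <- match(dat$gene_id, lay$gene_id)
    dat[[paste0(s, "_id")]] <- ifelse(is.na(m), NA_character_,
                                      paste0(s, ".", dat$gene_id))
    dat[[paste0(s, "_chr")]] <- lay$chr[m]
    dat[[paste0(s, "_start")]] <- lay$start[m]
    dat[[paste0(s, "_end")]] <- lay$end[m]
    dat[[paste0(s, "_strand")]] <- lay$strand[m]
    dat[[paste0(s, "_placed")]] <- lay$placed[m]
    dat[[paste0(s, "_class")]] <- ifelse(is.na(m), "none", "one2one")
    dat
  }
  dat <- add_species(dat, species[1], ref1)
  dat[[paste0(species[1], "_id")]] <- dat$gene_id
  dat <- add_species(dat, species[2], ref2)
  dat <- add_species(dat, species[3], focal)
  if (!is.null(classes)) dat[[paste0(species[2], "_class")]] <- classes
  sort_ortholog_table(ortholog_table(dat, species), species[1])
}

# drop genes from a layout (models focal-lineage loss)
drop_genes <- function(layout, gene_ids) {
  layout[!(layout$gene_id %in% gene_ids), , drop = FALSE]
}
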