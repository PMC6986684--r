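# Independent oracles used across tests. These deliberately avoid the
# package's internal code paths: amino acids come from Biostrings
# translation of DNAString objects, and pathway enumeration is written as
# a plain depth-first walk.

.aa_cache <- new.env(parent = emptyenv())
aa_of <- function(codon) {
  hit <- .aa_cache[[codon]]
  if (!is.null(hit)) return(hit)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                           no.init.codon = TRUE))
  .aa_cache[[codon]] <- aa
  aa
}

is_stop_oracle <- function(codon) aa_of(codon) == "*"

# Synonymous site count of one codon: for each position, the fraction of
# the three possible changes (excluding changes to stops) that preserve
# the amino acid.
oracle_syn_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; nonstop <- 0
    for (nuc in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      mut <- chars; mut[pos] <- nuc
      mut <- paste(mut, collapse = "")
      if (is_stop_oracle(mut)) next
      nonstop <- nonstop + 1
      if (aa_of(mut) == aa_of(codon)) syn <- syn + 1
    }
    if (nonstop > 0) total <- total + syn / nonstop
  }
  total
}

# Exhaustive pathway enumeration of syn/nonsyn differences between two
# codons, excluding pathways through intermediate stop codons (falling
# back to all pathways when every route is blocked).
oracle_path_counts <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  diffs <- which(ca != cb)
  if (length(diffs) == 0) return(c(syn = 0, nonsyn = 0))
  paths <- list()
  walk <- function(cur, remaining, syn, nonsyn, blocked) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1L]] <<- c(syn = syn, nonsyn = nonsyn, blocked = blocked)
      return(invisible(NULL))
    }
    for (pos in remaining) {
      nxt <- cur; nxt[pos] <- cb[pos]
      step_blocked <- blocked ||
        (is_stop_oracle(paste(nxt, collapse = "")) &&
           !identical(nxt, cb))
      s <- aa_of(paste(cur, collapse = "")) == aa_of(paste(nxt, collapse = ""))
      walk(nxt, setdiff(remaining, pos), syn + s, nonsyn + !s, step_blocked)
    }
  }
  walk(ca, diffs, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  use <- m[m[, "blocked"] == 0, , drop = FALSE]
  if (nrow(use) == 0) use <- m
  c(syn = mean(use[, "syn"]), nonsyn = mean(use[, "nonsyn"]))
}

all_sense_codons <- function() {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons[!vapply(codons, is_stop_oracle, logical(1))]
}

# Minimal single-region scenario builder used by several depth tests.
region_row <- function(contig = "chr1", start = 0, end = 100,
                       name = "parA", family = "THCAS-like", true_cn = NULL) {
  r <- tibble::tibble(contig = contig, start = start, end = end,
                      name = name, family = family)
  if (!is.null(true_cn)) r$true_cn <- true_cn
  r
}

uniform_depth <- function(contig = "chr1", from = 1, to = 100, depth = 30) {
  tibble::tibble(contig = contig, pos = seq(from, to), depth = depth)
}
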