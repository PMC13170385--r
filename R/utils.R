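# Internal helpers shared across modules.

.toRNA <- function(x) chartr("Tt", "Uu", toupper(x))

.toDNA <- function(x) chartr("Uu", "Tt", toupper(x))

.splitChars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# WC + GU wobble pairing rule on single uppercase RNA bases. N never pairs.
.canPair <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

.wcComplement <- function(b) {
    c(A = "U", U = "A", G = "C", C = "G")[[b]]
}

.applySubstitutions <- function(seq, subs) {
    if (!nrow(subs)) return(seq)
    ch <- .splitChars(seq)
    ch[subs$pos] <- subs$to
    paste0(ch, collapse = "")
}

# Strip Ensembl GFF3 feature-type prefixes ("gene:FBgn..." -> "FBgn...").
.normalizeFeatureId <- function(id) {
    sub("^(gene|transcript|mRNA|CDS):", "", id)
}

# Strip trailing version suffixes from gene identifiers before set algebra.
.normalizeGeneId <- function(id) {
    sub("\\.[0-9]+$", "", id)
}

# Locale-independent lexicographic order for deterministic output tables.
.lexOrder <- function(x) order(x, method = "radix")

.emptyBulges <- function() {
    data.frame(interruption = integer(0), side = character(0),
               start = integer(0), length = integer(0),
               stringsAsFactors = FALSE)
}
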