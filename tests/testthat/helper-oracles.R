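# Independent oracles used to cross-check the package's implementations.
# Both are deliberately written as literal enumerations, structured
# differently from the production code paths they validate.

# Hypergeometric enumeration oracle for the 2x2 exact test: point
# probabilities via choose(), two-sided by minimum-likelihood summation.
oracle_fisher_2x2 <- function(a, b, c, d, alternative = "two.sided") {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  pmf <- vapply(ks, function(k)
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)), numeric(1))
  p_obs <- pmf[ks == a]
  if (alternative == "greater") return(min(1, sum(pmf[ks >= a])))
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
}

# Brute-force rule-table oracle for the ACMG-AMP combining clauses: every
# clause of the guideline's combining table is enumerated literally.
oracle_acmg <- function(codes, mode = "strict") {
  codes <- unique(toupper(codes))
  k <- list(pvs = sum(codes == "PVS1"),
            ps = length(grep("^PS", codes)),
            pm = length(grep("^PM", codes)),
            pp = length(grep("^PP", codes)),
            ba = sum(codes == "BA1"),
            bs = length(grep("^BS", codes)),
            bp = length(grep("^BP", codes)))
  if (k$ba >= 1) return(list(verdict = "Benign", conflict_flag = FALSE))

  p_clauses <- c(
    k$pvs >= 1 && k$ps >= 1,
    k$pvs >= 1 && k$pm >= 2,
    k$pvs >= 1 && k$pm == 1 && k$pp >= 1,
    k$pvs >= 1 && k$pp >= 2,
    k$ps >= 2,
    k$ps == 1 && k$pm >= 3,
    k$ps == 1 && k$pm == 2 && k$pp >= 2,
    k$ps == 1 && k$pm == 1 && k$pp >= 4)
  lp_clauses <- c(
    k$pvs >= 1 && k$pm == 1,
    k$ps == 1 && (k$pm == 1 || k$pm == 2),
    k$ps == 1 && k$pp >= 2,
    k$pm >= 3,
    k$pm == 2 && k$pp >= 2,
    k$pm == 1 && k$pp >= 4)
  b_clauses <- c(k$bs >= 2)
  lb_clauses <- c(k$bs == 1 && k$bp >= 1,
                  k$bs >= 2 && k$bp >= 1,   # subsumed by Benign; harmless
                  k$bp >= 2)

  ptier <- if (any(p_clauses)) "Pathogenic"
           else if (any(lp_clauses)) "Likely pathogenic" else ""
  btier <- if (any(b_clauses)) "Benign"
           else if (any(lb_clauses)) "Likely benign" else ""
  if (nzchar(ptier) && nzchar(btier)) {
    v <- if (mode == "strict") "VUS" else btier
    return(list(verdict = v, conflict_flag = TRUE))
  }
  v <- if (nzchar(ptier)) ptier else if (nzchar(btier)) btier else "VUS"
  list(verdict = v, conflict_flag = FALSE)
}

# random evidence-code sets for the agreement sweep
random_code_sets <- function(n, seed) {
  vocab <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
             "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
  set.seed(seed)
  lapply(seq_len(n), function(i)
    sample(vocab, sample(0:8, 1)))
}
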