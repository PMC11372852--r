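# shared fixtures: all built in code, nothing on disk

quartet_labels <- paste0("S", 1:4)

# a fixed JC model reused across tests
jc <- jc_model()

# resolved quartet tree (S1,S3 | S2,S4) with given internal/terminal lengths
t2_tree <- function(t0, t1 = 0.01, t2 = 0.01, t3 = 0.01, t4 = 0.01) {
  parse_newick(sprintf("((S1:%g,S3:%g):%g,S2:%g,S4:%g);",
                       t1, t3, t0, t2, t4))
}

# proportion helper
prop_of <- function(x, value) mean(x == value)

# 3-standard-error binomial tolerance around p at sample size n
tol3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
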