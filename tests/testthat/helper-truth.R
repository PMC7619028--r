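# true genotype fitness pair for one study condition, from the generating
# truth list (fecundity ratio x sigmoid survival at the condition's dose)
truth_fitness_for_test <- function(truth_cmpd, concentration) {
  m_R <- truth_cmpd$R$mean_eggs / truth_cmpd$S$mean_eggs
  gp <- condition_fitness(
    list(R = list(m = m_R, fit = list(a = truth_cmpd$R$a, b = truth_cmpd$R$b)),
         S = list(m = 1, fit = list(a = truth_cmpd$S$a, b = truth_cmpd$S$b))),
    concentration
  )
  list(w_R = gp$R$w, w_S = gp$S$w)
}
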