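# eidt — individuality transfer across decision-making task conditions

People differ systematically in how they make decisions: how fast they learn
from reward, how much they explore, how quickly they respond. `eidt`
implements a transfer pipeline that captures those differences from a
person's behavior in one *source* task condition and predicts their
trial-by-trial choices in a different *target* condition — without ever
seeing their target-condition data.

The pipeline (EIDT: **e**ncoder, **i**ndividual latent representation,
**d**ecoder, **t**ask solver):

- an encoder GRU maps a behavioral sequence (states s_t, actions a_t,
  rewards r_t) to a low-dimensional latent vector z (default z ∈ R²);
- a linear hypernetwork decoder maps z to the full weight vector
  Θ_TS of a small GRU task solver;
- the task solver, teacher-forced on the logged target-condition history,
  outputs per-trial action probabilities π(a_t | history).

Training minimizes the mean per-trial negative log-likelihood of the logged
target actions over a pool of individuals who performed both conditions,
averaged over every (source block, target block) pair per individual, with a
90/10 participant-level split for validation-based early stopping.

The package also provides everything needed to validate the pipeline end to
end without human data:

- a simulator of the M-step value-guided task (M = 2, 3) with episode-wise
  drifting transition/reward probability pairs drawn from
  {(0.8, 0.2), (0.2, 0.8), (0.6, 0.4), (0.4, 0.6)};
- the Q-learning cognitive model (softmax policy with inverse temperature
  `q_it`, learning rate `q_lr`, discount `q_dr`, initial value `q_init`),
  its trial-wise likelihood, maximum-likelihood fitting, and the
  pool-average and individually-fitted baselines;
- a perceptual variant for single-shot digit decisions: a pluggable
  stochastic evidence source, an evidence-accumulating solver, a set-based
  encoder, and response-time binning (10 steps/s, S = 16);
- synthetic heterogeneous agent populations and dataset builders;
- evaluation tools: trial-wise NLL, behavior-match rate, cross-individual
  Gamma regression of performance on latent distance, on-policy
  comparisons, and the latent-vs-parameter regression;
- a data-quality exclusion filter (IQR method on mean reward, action bias,
  response time);
- a command-line pipeline (`inst/scripts/eidt-cli`): `simulate-pop`,
  `train-eidt`, `transfer`, `evaluate`, `cross-indiv`.

## Worked example

```r
library(eidt)

# a pool of 12 synthetic Q-learning agents playing the human protocol
pop <- sample_qpopulation(population_spec(12, seed = 7))
ds  <- build_mdp_dataset(pop, seed = 8)
ds
#> <behavioral_dataset> task=mdp, 12 individuals, 9000 trials
#>   conditions: 2step (M=2), 3step (M=3)

# train a 2-step -> 3-step transfer model (small demo budget)
m <- train_eidt(ds, "2step", "3step",
                eidt_config(max_epochs = 40, patience = 40, seed = 1))

# predict a held-out agent's 3-step behavior from its 2-step behavior only
agent <- simulate_agent(qparams(0.61, 0.9, 4.5, 0), seed = 99,
                        participant_id = "new")
z <- individual_latent(m, agent)
round(z, 3)
#> [1]  0.243 -0.183
tgt <- Filter(function(b) b$condition == "3step", agent$blocks)[[1]]
P <- transfer_predict(m, agent, tgt)
c(nll = nll_metric(P, tgt$trials$action),
  match = match_rate(P, tgt$trials$action))
#>       nll     match
#> 0.6422987 0.6466667
```

The latent vector `z` summarizes the new agent's decision tendencies from
its source-condition blocks alone; `transfer_predict` scores its logged
3-step choices teacher-forced, so `nll` is the mean per-trial surprise
(ln 2 ≈ 0.693 is chance for two actions) and `match` the fraction of trials
where the model's most probable action equals the agent's actual choice.

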