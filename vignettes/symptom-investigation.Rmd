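---
title: "Association-guided symptom investigation and diagnosis dialogues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association-guided symptom investigation and diagnosis dialogues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An automated diagnosis dialogue starts from a patient's self-report (the
*explicit* symptoms), investigates further symptoms by asking questions
(uncovering *implicit* symptoms, each of which the simulated patient
confirms or denies), and finally commits to a disease.  A good agent asks
few, *relevant* questions — queries that a human patient would recognise
as connected to their complaint — and still diagnoses accurately.

`sidial` implements such an agent as a two-level ("options"-style)
deep-Q-learning policy over a corpus of 9 disease groups × 10 diseases ×
266 symptoms, together with the association machinery that guides and
rewards relevant questioning, and the evaluation metrics — including the
Investigation Relevance Score (IReS) — that quantify it.

## The model

**Hierarchy.**  A *controller* policy observes the dialogue state and
either activates one of nine *department* (disease-group) policies or
triggers the disease classifier.  An activated department policy queries
symptoms from its group's observed-symptom set, one per turn, until it
returns control or the global limit of N = 28 queries is reached.  Each
policy is an independent Q-learner: a single-hidden-layer value network
trained by replay-buffer SGD on the TD loss, with an epsilon-greedy
behaviour rule (epsilon = 0.1, no annealing) and a periodically frozen
target network.  Both the standard DQN maximum-target rule and the Double
DQN decoupled rule (`mode = "ddqn"`) are implemented; the Double DQN
target is never larger than the DQN target on the same batch, which is
the point of the decoupling.

**Worker action values.**  A department policy picks the symptom with the
highest Q-value among its `N_i` symptoms plus one return-control action.
Department symptom sets are derived from the training records of each
group, so the hierarchy's masking is data-driven: a worker can never
query a symptom its department has never seen, and the controller never
queries symptoms at all.

**Terminal credit.**  A department activation is credited with the
discounted sum `sum_i gamma_c^i * r_i` of the per-turn internal rewards
its worker earned during the subtask (gamma_c = 0.9); the diagnose action
receives the raw terminal reward, `+t1*N` on a correct diagnosis.  The
success case is itself part of the department agent's internal critic, so
the terminal reward is additionally credited to the last worker
transition — workers share in the outcome of the diagnosis their
investigation enabled, which is what makes investigation quality
learnable at all.  The failure penalty `-t1*N` (wrong disease, or
turn-limit expiry) mirrors the success magnitude; only the success case
is standard, the symmetric failure value is this package's choice.  A
turn-limit failure lands inside the offending subtask and therefore also
flows into that activation's discounted controller reward.

**Association module.**  From the training split a symptom–symptom
co-occurrence graph is counted: every unordered pair of status-true
symptoms in a record increments the pair count.  The directional
association from `s_i` to `s_j` is the row-normalised count
`n(s_i, s_j) / sum_k n(s_i, s_k)`; rows with zero total score 0
everywhere rather than erroring.  Three consumers use it:

* the *context association* `as_t` of a queried symptom is its summed
  association over all confirmed symptoms (self-report included), with
  the queried symptom as the row anchor;
* the *top-K recommendation* ranks unconfirmed symptoms by the summed
  association with each confirmed symptom as its own row anchor — the
  two argument orders deliberately differ, following the printed
  formulations; ties break by vocabulary index, and the empty-context
  fallback ranks by global co-occurrence frequency (self-reports are
  non-empty in practice, so this path is rare);
* the IReS evaluation metric (below).

**Critics.**  Each worker turn is scored by three critics:
internal (`+t2*N` for a confirmed query, `-t3*N` for a repetition, 0
otherwise), recommendation (`+t4` if the query was in the current top-K
recommendation, else `-t5`), and association (`+t4` if `as_t > h`, `+1`
if `l < as_t <= h`, `-t5` otherwise).  The total worker reward is
`r_d + (r_rr + r_ar)`.  The shaping constants default to
`t = (3, 2, 2, 15, 2)` with N = 28 — so success pays +84, a match +56, a
repetition −56, a recommended query +15.  Ablation flags zero the
recommendation and/or association critics; with both off the total
reward equals the internal reward exactly, which is the unguided
hierarchical baseline.

The association thresholds `l` and `h` have no published values.  The
defaults 0.05 and 0.20 were chosen once so that the middle band is
reachable at the association magnitudes a 266-symptom corpus produces
(row-normalised scores against a handful of anchors are typically a few
hundredths); both are configuration keys.  The middle-band reward is the
bare `+1` as printed; whether it should scale with the `t` constants is
an open question we did not second-guess.

**State encoding.**  Every policy consumes the same fixed layout over a
vocabulary of V symptoms: a true/false/unknown indicator triple per
symptom (3V), a one-hot of the last queried symptom (V), a K-hot of the
current recommendations (V), the turn scaled by N, and the previous
turn's shaped reward scaled into [−1, 1] by the maximum attainable
magnitude — bounded features stabilise Q-learning.  Total length 5V + 2.

**Disease classifier.**  A two-layer network (hidden width 256,
rectified) maps the 3V status encoding to a softmax over all diseases.
It is trained once, before policy learning, on fully revealed records —
every recorded symptom set to its recorded status, everything else
unknown — and then frozen.  Staged training isolates the policies'
credit assignment from classifier drift and makes runs reproducible.
Unknown symptoms keep their own indicator rather than being collapsed to
"false", preserving the distinction that partial observation creates.
Optimisation is mini-batch SGD with classical momentum 0.9 and learning
rate 0.02 — plain SGD at the policies' printed rate is far too slow for
a 90-class problem with ~800 inputs.

Raw record encodings, however, are not what the classifier sees at
dialogue time: an episode reveals only the implicit symptoms the agent
queried, and the simulated patient *denies* queried symptoms absent from
the record, producing "false" statuses that never occur in the records
themselves.  Trained naively, the classifier degrades the moment the
agent investigates.  Each training example is therefore stochastically
masked per batch: every implicit symptom is hidden (back to unknown)
with probability `implicit_dropout = 0.5`, and a Poisson(3) number of
random unknown symptoms are revealed as false
(`negative_augmentation`).  This is the stochastic-masking counterpart
of fine-tuning on episode-revealed symptom sets, and it aligns the
classifier's training distribution with the partial, denial-bearing
inputs a dialogue produces; both knobs are configuration keys and 0
disables them.

## The patient simulator

An episode starts from a sampled record: explicit symptoms are revealed
at their recorded status, the turn counter is zero.  The simulator
answers queries from the record; a symptom absent from the record is
denied — the standard goal-oriented convention, and the only consistent
reading when records store a sparse symptom list.  Recorded-false
implicit symptoms are denied identically.  Repeating a known query
changes nothing except the turn counter; its punishment is the internal
critic's job (during greedy evaluation, already-answered symptoms are
masked instead — both behaviours are switchable, and masking stays off
during training so the repetition penalty remains learnable).

Dialogue length counts agent symptom queries only.  Because a worker may
return control without consuming a turn, the turn limit alone cannot
bound an episode; after 2N controller decisions the diagnose action is
forced.  This guard is transient plumbing — trained controllers diagnose
long before it binds.

The diagnose action is masked until at least one department has been
activated (`diagnose_from_start = FALSE`, switchable).  An unrestricted
diagnose action lets short-horizon training collapse into a
never-investigate policy that classifies from the self-report alone —
degenerate for a system whose purpose is symptom investigation, and it
mirrors the clinic metaphor: the receptionist routes the patient to a
department before any diagnosis is made.

## Evaluation metrics

From a set of episode logs the package computes: success rate; average
dialogue turns; average total reward; AMR (mean over dialogues of
confirmed queries / all queries, %) and AMR2 (normalised instead by the
patient's true implicit-symptom count, %); top-k disease coverage from
the classifier's final ranking; a group-level confusion matrix of failed
diagnoses (the diagonal isolates wrong-disease-right-group errors, the
signature of within-group symptom overlap); and IReS:

* **IReS-1** — for every query turn, the association of the queried
  symptom with each self-report symptom, summed; averaged over all query
  turns.
* **IReS-2** — identical, but anchored on all symptoms confirmed before
  the turn (self-report included).  Since the anchor set grows, IReS-2
  can exceed 1.

The printed formulation divides by `t * sum(n_i)` with `t` undefined; we
take `t = 1`, i.e. a per-query-turn average, the only reading consistent
with published IReS-2 values above 1 alongside IReS-1 values below 1 for
single-symptom self-reports.  The anchor snapshot is taken before the
turn's answer is applied, so a query never anchors itself, and
repetition queries still count as turns the patient experienced.

All metrics are pure functions of the logs: episodes serialised to JSON
lines re-score identically.

## The synthetic corpus generator

The generator emulates the published structure of the diagnosis corpus:
9 groups × 10 diseases, 266 symptoms, one self-report symptom and 2.6
implicit symptoms per record on average, 30,000 records by default,
balanced across diseases.  A configurable fraction (default 0.15) of the
vocabulary is shared across all groups; the remainder splits evenly into
group pools.  Each disease draws a fixed 12-symptom profile from its
group pool plus the shared commons; each record then samples
`1 + Poisson(mean_explicit − 1)` explicit and `Poisson(mean_implicit)`
implicit symptoms from its disease's profile (truncated to the profile).
Because a group pool (~25 group-specific + ~40 shared symptoms) is
smaller than ten 12-symptom profiles, same-group profiles overlap
heavily — deliberately, as within-group confusion is the dominant
failure mode the group confusion matrix is meant to expose.  Negated
implicit findings are supported (`negative_implicit_rate`) but default
to 0; the corpus's class balance and negation prevalence are not
published, so both are configuration keys.

What the generator does **not** emulate: real symptom marginals and
their heavy tails, correlated noise between diseases of different
groups, reporting noise (a patient denying a symptom they have), and
free-text utterances.  Tests passing on this corpus therefore
demonstrate the mechanics and the learning dynamics of the method, not
clinical performance.

The fully separable 3-group × 3-disease corpus used in the learnability
test is built directly through the dataset constructor with disjoint
3-symptom profiles, because independent pool sampling cannot guarantee
disjointness at that size; separability by construction is the point of
that fixture.

## Numerical choices and problem sizes

Value networks use He-initialised single-hidden-layer MLPs written in
plain matrix code; the policies use the printed learning rate 0.0005,
batch size 100, replay capacity 10,000, target sync once per epoch, and
5 replay updates per policy per epoch.  All randomness flows through R's
seeded generator; `train_agent()`, `train_classifier()`,
`generate_synthetic_dataset()` and `split_dataset()` are bit-for-bit
reproducible given their seeds and restore the caller's RNG state.

The test suite runs at desk scale, chosen once: the learnability check
trains 200 epochs × 20 episodes with hidden width 64 on the separable
corpus; the directional ablation uses a 1,800-record default-structure
corpus, 15 epochs × 30 episodes, hidden width 64, learning rate 0.005
(the printed 0.0005 is calibrated to 5,000-epoch training and shows no
measurable movement at desk scale), five seeds, with one classifier per
seed shared by the guided and unguided agents so the comparison is
paired on everything except the critics.  Full-scale
training (5,000 epochs × 100 dialogues on 24,000 records) is what the
published headline numbers require and is out of scope here; the
package's claims at desk scale are directional, not absolute.

## Known limitations

* The flat baseline ranks diseases by Q-values, so its "coverage" is a
  value ranking, not a probability ranking.
* No annealing, prioritised replay, or gradient clipping; instability at
  aggressive learning rates is handled by the conservative defaults.
* The simulator is binary (yes/no); "not sure" answers and natural
  language are out of scope.
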