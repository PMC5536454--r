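---
title: "Methods: a cellular Potts model of tumor micro-evolution under fluctuating nutrient supply"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cellular Potts model of tumor micro-evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`pottsevo` simulates a confluent monolayer of epithelial cells on a periodic
2-D square lattice using the cellular Potts model (CPM). Every lattice site
carries an integer identifier; a cell is the domain of sites sharing one
identifier, identifier 0 is cell-free medium, and a small set of immobilized
"endothelial" (EC) discs act as cross-sections of blood vessels. Motion is a
Markov chain of copy attempts: a random site's identifier is proposed into a
random neighbor site and accepted with the Metropolis probability
$\min\{1, e^{-\Delta H/T}\}$. One Monte Carlo step (MCS) is $N$ attempts
($N$ = lattice sites), calibrated to one minute; one site is 2 µm, so the
published 200×200 lattice is a 400 µm × 400 µm tissue patch.

The goal function has three parts.

* **Volume**: $H_v = \sum_i \frac{\lambda_v(i)}{V^T(i)}\,(V(i)-V^T(i))^2$.
  Normalizing the incompressibility by the target volume makes freshly
  divided daughters effectively stiffer, which suppresses division waves in
  a compressed monolayer; for a homogeneous population with common target
  volume $c$ it reduces to the classic CPM volume term divided by $c$.
* **Adhesion**: contact energy
  $J^{\mathrm{eff}} = J(\tau,\tau') - \sum_{a,b}k_{a,b}\min[\rho_a,\rho_b]$,
  with cell-adhesion-molecule matching on cell–cell and cell–vessel
  contacts and matrix-adhesion matching on cell–medium contacts (all
  $k=1$). With $J_{\max}=100$, $J(c,c)=J(c,EC)=J_{\max}$,
  $J(c,m)=J_{\max}/2$, fixed vessel CAM density $J_{\max}$ and medium MAS
  density $J_{\max}/2$, the published molecule-density ranges make
  $J^{\mathrm{eff}}$ span exactly $[0,J_{\max}]$ (cell–cell/vessel) and
  $[0,J_{\max}/2]$ (cell–medium).
* **Chemotaxis**: a pure $\Delta H$ bias (not part of $H$):
  $\Delta H_\chi = -\sum_{s\in\{g,O_2,l\}}\chi_s\,(s(x')-s(x))$ for the
  extending cell, so positive $\chi$ is attraction. The source text prints
  the opposite sign, which would make the coefficients repulsive and
  contradict its own description of evolved lactate chemorepulsion; we use
  the attractive orientation. Retractions are treated symmetrically (a cell
  also resists losing high-concentration sites); this is the standard CPM
  ambiguity, decided once and applied everywhere.

The acceptance rule as printed ($e^{+\Delta H/\mu}$ for uphill moves) is not
a probability; the standard Metropolis form is used. The Metropolis noise
$T$ (the text's $\mu$) is not published; default 50, on the scale of the
cell–medium surface tension, which gives visible membrane fluctuation
without melting cells.

Copies from or into vessel sites are rejected unconditionally (vessels are
immobilized), and identity copies are skipped as no-ops. Both the contact
neighborhood and the copy-candidate neighborhood default to Moore
(8-neighbor); the source is silent on this and both are configurable.

# Nutrient fields and vessels

Glucose, oxygen and lactate diffuse on the same lattice (periodic boundary)
with zero decay; active vessels clamp $g=1$, $O_2=1$, $l=0$ (vessel-level
units). A blocked vessel is, by default, inert — its sites evolve freely by
diffusion — matching the implementation-level description in the source;
the alternative reading ("kept at zero") is available as
`inactive_vessel = "zero"`. Every MCS each vessel flips active/blocked with
probability $P$; blocking and unblocking share $P$, so the long-run active
fraction is 1/2 for every $P$ and only the dosage pattern (tortuosity)
changes. Three laws for $P$: constant; geometric in time
$P(t+1)=rP(t)$ floored (the published progressive-tortuosity run uses
$P(0)=0.5$, $r=0.999876$, floor $10^{-3}$); and a density feedback
$P(\rho)=0.499\rho+0.001$ on tissue coverage.

**Numerics.** The explicit 5-point scheme with diffusion number
$\mu = D\,\Delta t/\Delta x^2 \le 1/4$ needs 600 substeps/MCS for oxygen
and lactate at their physical $D=10^{-11}$ m²/s — that is what runs, and it
conserves mass exactly on the periodic lattice. Glucose at
$D=10^{-9}$ m²/s would need 60,000 substeps/MCS; more importantly, at a
truly physical glucose diffusivity the field is flat to $\sim10^{-2}$ at
any attainable uptake, glucose can never locally deplete, and the model's
starvation stage is unreachable. The reference implementation's
finite-difference solver substeps far below the physical stability
requirement, so its *effective* glucose transport is likewise much slower
than physical. We therefore cap glucose at the same 600 substeps by default
(effective in-lattice diffusivity 150 site²/MCS for all species) and treat
this as a model definition, not an approximation error. A quasi-steady
relaxation solver (`glucose_solver = "relax"`) is provided for the
physical-limit regime.

Per-site uptake is clamped by availability (concentrations stay
non-negative), and respiration is additionally limited by the oxygen
present at the site.

# Metabolism

Each MCS a cell takes up glucose over its surface sites (sites with a
Moore neighbor outside the cell) with Michaelis–Menten kinetics,
$u_g = \frac{N_G}{S}\,\frac{V_m\,g}{K+g}$, where the transporter count
follows the hypoxia-compensation law
$N_G = N_0(\alpha_r-2)/(\alpha_r-(\alpha_r-2)h)$. A fraction $h$ (the
hypoxia factor, a HIF1-α proxy) of glucose is fermented (2 ATP + 2 lactate
per glucose); $1-h$ is respired ($\alpha_r = 38$ ATP, 6 O₂ per glucose,
ROS as by-product). The compensation makes energy per MCS exactly
independent of $h$ at fixed surface glucose — there is no intrinsic
selection advantage to either metabolic mode; the Warburg shift that
emerges is environmental, not hard-wired.

The switch itself combines two Hill arms with a one-MCS signaling delay:
$h' = 1-\big[\tfrac{O_2^{n}}{\kappa_h^{n}+O_2^{n}}\big]\big[1-\tfrac{\zeta^{n}}{\kappa_\zeta^{n}+\zeta^{n}}\big]$,
on the cell-mean oxygen (oxygen is assumed membrane-permeable) and the ROS
level $\zeta$. ROS follows
$\zeta' = (1-\omega_\zeta)\zeta + (1-h)\,U_g$ with $\omega_\zeta = 0.1$;
the printed update lacks the persistence factor and can go negative, so the
exponential-decay form is used (the fixed point for constant respiration
input $c$ is $c/\omega_\zeta$). The ROS arm is what locks fermentation in:
once respiration has charged $\zeta$ past $\kappa_\zeta$, $h$ stays high
even after oxygen returns.

Cells are processed in ascending identifier order; each cell sees the field
state left by its predecessors within the MCS. Transporter demand uses the
cell's surface glucose before its own consumption.

# Growth, division, death

Net energy $E_{prod}-E_m$ drives biomass:
$dV^T = \alpha\,\mathrm{net} - \beta\,(V^T-V)\,|V^T-V| -
\gamma\,\Theta(\zeta-\theta_R)$ for positive net; the pressure term is
oriented to relax $V^T$ toward $V$ (a compressed cell grows more slowly —
the printed sign does the opposite and contradicts the stated intent), and
ROS above tolerance shrinks the cell. Negative net is paid from biomass
(catabolism, $dV^T=\alpha\,\mathrm{net}$); a cell whose target volume
reaches zero is dead and its sites become medium. $E_m$ is subtracted once
(the source subtracts it in both the energy and the growth equation; that
double-counting is collapsed).

Division is probed once per cell per MCS through the sigmoid gate around
the division volume $V_D$ with window $w=0.05\,V_D$: zero below $V_D-3w$,
one above $V_D+3w$. A dividing cell is bisected by a line through its
periodic centroid oriented along its axis of least extent (deterministic
given the lattice), target volume is shared exactly in half, and both
daughters independently run a mutation pass. Random apoptosis hits 0.1 %
of cells per MCS; apoptotic cells shrink their target volume by 1 site/MCS
until removal.

# Evolution

Ten phenotype parameters (incompressibility, division volume, two
adhesion-molecule densities, three chemotaxis coefficients, growth signal
$N_0$, two Hill thresholds) mutate independently with probability $\mu_p$
per parameter per pass, by a Gaussian step of the published
parameter-specific size, reflected (iteratively) into the published range —
so an unselected parameter performs a random walk whose stationary
distribution is uniform on its range. At $t=0$ every cell runs exactly one
pass to seed heterogeneity. The published table lists the
incompressibility's initial value (25) above its maximum (20); the maximum
is raised to 25 here so the initial value is admissible.

# Parameter choices that are not published

$V_m, K, E_m, n_h, n_\zeta, \alpha, \beta, \gamma, \theta_R$ and $T$ live
in the reference implementation's configuration files, not in the text.
They were calibrated **once**, against the homeostasis requirement (a
non-mutating tissue under stable vessels keeps constant cell number, full
coverage, no lactate) and the initial-state consistency requirement (an
unmutated resting cell is nearly fully respiratory, with ROS well below its
switching threshold, near energy balance), and then frozen:

| parameter | value | role of the constraint |
|---|---|---|
| $V_m$ | $10^{-4}$ | healthy per-cell uptake $\approx0.016$/MCS keeps $\zeta^\* \approx 0.16 \ll \kappa_\zeta$; an order-1 rate would exceed per-site availability ~15-fold, leaving every cell clamp-limited and destroying the GLUT compensation |
| $K$ | 0.5 | half-saturation at mid vessel-level |
| $E_m$ | 0.3 | ~half of resting production: survival with margin, catabolism under blockage |
| $n_h = n_\zeta$ | 4 | healthy tissue sits cleanly on the respiratory side of both Hill arms |
| $\alpha$ | 0.5 | vacancy refill (doubling in a few hundred MCS) outpaces the 0.1 %/MCS turnover |
| $\beta$ | 0.01 | equilibrium pressure a few sites |
| $\gamma$, $\theta_R$ | 0.05, 1 | ROS toxicity engages only for evolved high consumers (~6× resting ROS) |
| $T$ | 50 | membrane fluctuation without cell fragmentation |

# Initial conditions

Cells tile the lattice as 5×5 blocks ($V = V^T = 25$); four vessel discs of
radius 3 sit at the lattice quarter-points (or are placed randomly).
Before the production run the fields equilibrate in an *initial regime*:
cells metabolize fully respiratorily but cannot move, grow, divide, die or
mutate, vessels stay active, and the regime ends when the summed glucose
and oxygen fields change by less than 5 % over 100 MCS — hence no lactate
exists at release. ROS is allowed to settle to its respiratory fixed point
during the regime so released cells start self-consistent; the hypoxia
factor is recomputed once on release.

# What the scaled-down experiments emulate — and what they do not

The published experiments use a 200×200 lattice, four vessels ~100 sites
apart, and $10^5$ MCS. The package's test profile shrinks the lattice but
**keeps the source spacing**: an 80×80 lattice with a single vessel
preserves (periodically) the ~80–100-site diffusion distances that make
local oxygen and glucose depletion possible (on a 60×60 lattice with four
vessels no depletion can occur at any attainable uptake — the vessels are
simply too close). Evolution speed scales with generations, not wall-clock
MCS, so the staged-progression reproduction runs at the top of the
published mutation-rate sweep (90 %), using the source's own observation
that the mutation rate changes the tempo of the stages but not their
order. A green scaled run therefore establishes the mechanism (selection
for high $N_0$, oxygen-first depletion, ROS-locked fermentation, evolved
lactate chemorepulsion) — not the published full-scale numbers
(single-mutant persistence counts, coverage halving, emergent
$P(\rho)\approx0.27$), which require full-size replicate sets and the
unpublished configuration constants.

Two scale artifacts of the compressed runs are worth naming. First, the
post-starvation **population decline is mild** compared to the published
halving: evolved cells divide at small division volumes, so near-vessel
division churn replaces distant starvation deaths almost one-for-one; only
the downturn itself, and its position after glucose depletion, is asserted.
Second, the **combined-chemotaxis signal is weak in a single replicate**:
the population is clonal, so the mean of $\chi' = \chi_g+\chi_{O_2}-\chi_l$
carries lineage-drift noise of order ±0.5 (mutation step 0.1, a few
effectively independent lineages), comparable to the selection signal at
these horizons. The published result averages ten full-size replicates of
$10^5$ MCS. The acceptance run asserts the direction (late $\chi'$ above
early, evolved $\chi_l$ negative) on a fixed seed and makes no claim about
magnitude.

# Known limitations

* Cell-cycle structure, acid toxicity, necrotic-core mechanics, vascular
  remodeling and 3-D transport are out of scope, as in the source model.
* The per-MCS hook order (copy attempts → vessels/fields → metabolism →
  HIF/ROS → growth → division+mutation → death) fixes what the source
  leaves open beyond "metabolism → division → mutation".
* Quantitative trajectories depend on the unpublished constants above and
  are matched qualitatively, not numerically.
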