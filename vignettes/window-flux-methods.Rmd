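---
title: "Methods: Brownian window fluxes, hybrid simulation and source recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Brownian window fluxes, hybrid simulation and source recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradsense)
```

## The model

A steady point source at $x_0$ emits Brownian particles (diffusivity $D$,
unit injection rate) into an unbounded planar domain containing a
reflecting obstacle. $N$ small absorbing windows of common arclength
$\varepsilon$ sit on the obstacle boundary; the rest of the boundary
reflects. The steady-state density solves

$$-D\,\Delta P_0 = \delta(x - x_0),\qquad
  \partial_n P_0 = 0 \text{ (reflecting part)},\qquad
  P_0 = 0 \text{ (windows)},$$

and the quantity of interest is the *splitting probability* $P_k$: the
share of the total window flux captured by window $k$. Planar Brownian
motion is recurrent, so the total absorbed flux is one and
$\sum_k P_k = 1$; the splitting probabilities are therefore genuine
probabilities, independent of $D$ and of the injection rate.

Three geometries are supported:

* `half_plane()` — the domain on one side of a straight reflecting line,
  windows are intervals of the line;
* `exterior_disk(R)` — free space outside a reflecting disk, windows are
  arcs of the circle;
* `disk_in_strip(R, a)` — the same disk inside a strip with reflecting
  walls at $y = \pm a$ (hybrid simulation only; no closed-form
  Neumann–Green's function is implemented for this geometry).

All lengths are nondimensional; a natural scaling sets the window
separation (or the disk radius) to one.

## Matched asymptotics

In the narrow-escape regime ($\varepsilon \ll d_{ij} = |x_i - x_j|$) the
solution is a Neumann–Green's function outer solution glued to a
logarithmic inner solution at each window. The method-of-images kernels
are

$$G_{\mathrm{hp}}(x, x_0) = -\tfrac{1}{2\pi}\left(\ln|x - x_0| +
  \ln|x - \bar x_0|\right), \qquad
  G_{\mathrm{disk}}(x, x_0) = -\tfrac{1}{2\pi}\left(\ln|x - x_0| +
  \ln\bigl|\tfrac{R^2}{|x|^2}x - x_0\bigr|\right),$$

with $\bar x_0$ the mirror image across the line. Matching yields the
linear system solved by `window_system()`: for $i = 1..N$,

$$G(x_i, x_0) + \sum_{k \ne i} A_k \ln\frac{d_{ik}}{\varepsilon} + C = 0,
 \qquad \pi \sum_k A_k = 1,$$

with $P_i = \pi A_i$. For $N = 2$ the closed form is
$P_i = \frac12 + \frac{\pi}{2}\,[G(x_i,x_0) - G(x_j,x_0)]/\ln(d/\varepsilon)$
(`splitting_closed_form()`); the sign is fixed by the matching
conditions so that the window nearer the source receives the larger
flux — the package's hybrid simulator confirms this ordering. For
$N = 3$ an explicit elimination (`three_window_explicit()`) gives
$A_2, A_3$ through the determinant
$\Delta_{123} = (L_{12}+L_{13}-L_{23})^2 - 4 L_{12} L_{13}$,
$L_{ij} = \ln(d_{ij}/\varepsilon)$, with right-hand sides
$b_i = G(x_i,x_0) - G(x_1,x_0) + L_{1i}/\pi$; it matches the generic
solve to $10^{-10}$ and is the forward map used by the inversion. The
linear solve guards against near-degenerate window layouts by raising an
error when the condition number exceeds $10^{12}$.

### Accuracy of the leading-order formulas, and the capacity option

The formulas above carry the matching constant $\ln\varepsilon$. The
exact inner problem for an absorbing slit of arclength $\ell$ has
far-field constant $\ln(\ell/4)$ — the logarithmic capacity of a
segment is a quarter of its length. The leading-order form therefore
overstates flux differences by a relative factor
$\approx \ln 4 / \ln(d/\varepsilon)$, which is *not* small at practical
window sizes: at $\varepsilon = 0.1$, $d = 1$ it is a 30–40% relative
error in $P_i - \tfrac12$.

The test suite quantifies this against an independent spectral solution
of the mixed boundary-value problem (conformal map onto the unit disk,
Fourier-basis least squares; `tests/testthat/helper-oracle.R`). For two
windows at $z = \pm\tfrac12$, $\varepsilon = 0.1$, source $(1, 2)$:

| quantity | $P_1$ |
|---|---|
| leading-log closed form (`matching = "log_eps"`) | 0.5871 |
| spectral solution of the exact problem | 0.5542 |
| capacity-matched form (`matching = "capacity"`) | 0.5544 |
| hybrid simulation ($n = 2\cdot10^4$, default step) | 0.544 |

All analytic functions accept `matching = "capacity"`, which replaces
$\varepsilon$ by $\varepsilon/4$ in every logarithm. The default remains
the leading-order convention `"log_eps"`, because the package's
reference values, the sensitivity/detection-threshold formulas and the
recovery round trips are all stated in it, and the inverse problem is
convention-consistent: fluxes generated and inverted under the same
convention recover the same source. A consequence worth stating plainly:
a *simulated* flux vector is a slightly different forward model than the
leading-order analytic one, so exact agreement between the two at
$\varepsilon = 0.1$ should not be expected at Monte-Carlo precision of
$10^{-3}$; the simulator agrees with the spectral solution instead.

## Sensitivity and detection threshold

For two half-plane windows a distance $d$ apart and a source at polar
position $(L, \theta)$ (angle from the boundary normal),
`sensitivity_ratio()` evaluates

$$r(d, L, \theta) = \left|\frac{1}{2\ln(d/\varepsilon)}
 \ln\frac{d^2/4 + L^2 - L d \sin\theta}
         {d^2/4 + L^2 + L d \sin\theta}\right|
 \;\xrightarrow{L \gg d}\; \frac{d\,|\sin\theta|}{L \ln(d/\varepsilon)},$$

the absolute flux difference $|P_1 - P_2|$. Its maximum over $\theta$ at
$L = 10d$, $\varepsilon = 0.1$ is $\approx 4.35\%$: beyond roughly ten
window separations, percent-level flux noise defeats direction sensing.
For a disk, the optimal window placement is diametrically aligned with
the source, giving the detection threshold
$f(L) = \ln\frac{L+R}{L-R} / \ln\frac{2R}{\varepsilon}
 \approx \frac{2R}{L \ln(2R/\varepsilon)}$
(`detection_threshold()`, `detection_threshold_asymptotic()`); with two
independent particle classes the product $f^2$ applies, decaying as
$1/L^2$.

## Hybrid analytical–stochastic simulation

`splitting_simulate()` never tracks a trajectory outside a bounded
working region:

1. **Injection.** The particle is placed directly on an inner artificial
   boundary — a (half-)circle of radius $R_e$ enclosing the windows, or
   the strip cross-section at $|x| = d_e$ — drawn from the exact
   first-hitting density of that boundary seen from the source. The
   free-space density is the Poisson kernel
   $\frac{1}{2\pi}\frac{\rho^2-1}{\rho^2 - 2\rho\cos\Delta\theta + 1}$,
   $\rho = r/R_e$, i.e. a wrapped-Cauchy law with concentration
   $q = R_e/r$, sampled by its closed-form inverse CDF
   $\Delta = 2\arctan[\frac{1-q}{1+q}\tan(\pi(u - \tfrac12))]$. The
   half-plane and strip densities are method-of-images symmetrizations
   of the same law, so they are sampled exactly by drawing the
   underlying wrapped-Cauchy deviate and *folding* it across the
   reflecting boundary — no rejection step anywhere. The semi-strip
   density derives from the strip Green's function
   (`green_semistrip()`), whose closed form the suite verifies against
   its eigenfunction series; the mode frequency is $\omega = \pi/a$ for
   a strip of width $a$ (the hybrid maps the physical half-width-$a$
   strip onto a width-$2a$ semi-strip).
2. **Euler stepping.** Inside the working region,
   $x \leftarrow x + \sqrt{2 D \Delta t}\, w$. The fine step obeys
   $\sqrt{4 D \Delta t} = \varepsilon/3$, keeping the root-mean-square
   displacement a third of the window size. Away from the windows the
   step grows with the distance to the nearest absorbing structure (rms
   $=$ distance/3), which leaves the path law unchanged (a
   position-dependent time change of Brownian motion) while cutting the
   cost of far excursions by orders of magnitude; near the *curved*
   obstacle the same rule is applied to the obstacle distance so that
   reflection chords stay short. Straight boundaries (the half-plane
   line, the strip walls) are handled by exact folds at any step size.
3. **Absorption and reflection.** Classification uses the full step
   *segment*: a crossing inside a window absorbs; elsewhere the step is
   specularly reflected (iterated for the rare multi-bounce chords);
   endpoint-only tests would undercount absorption at finite
   $\Delta t$.
4. **Re-injection.** A trajectory passing the outer boundary ($R_o$, or
   $|x| > d_o$ in the strip) is terminated at its escape point $T$ and
   re-injected on the inner boundary from the exit density *seen from*
   $T$. Because the obstacle lies entirely inside the inner boundary,
   this renewal is exact, preserving the angular correlation of returning
   trajectories; absolute time is deliberately not tracked, since the
   splitting probabilities are time-free. Absorption is certain by
   recurrence; a safety cap (default $10^4$ re-injections) turns a
   mis-sized $R_e/R_o$ pair into a loud error instead of a silent bias.

Defaults: $R_e = 1.5\times$ and $R_o = 3\times$ the obstacle extent,
inside the range over which the stability suite verifies that estimates
are invariant to the artificial radii. The trajectory loop is C++
(Rcpp) with a xoshiro256++ generator seeded from the user's seed, so a
`seed` reproduces a run exactly; the R-level samplers
(`sample_exit_point()`, `inject()`, `euler_step()`) use R's RNG under
`set.seed()`.

**Known discretization bias.** With the default fine step the
segment-crossing rule slightly under-resolves window-edge excursions;
the residual bias on $P_1$ is about $-0.01$ on the most asymmetric disk
reference case and $-0.005$ on the half-plane one, shrinking first-order
in the rms step (the suite's convergence test halves the step). Use a
smaller `dt` when Monte-Carlo errors below $10^{-2}$ matter.

## Source recovery

One observed flux ratio constrains the source to a curve. At window
centres on the obstacle boundary both Green's kernels reduce to
$-\frac{1}{\pi}\ln|x_i - x_0|$ (plus a window-independent constant), so
the two-window level set $P_2 = \alpha$ is the Apollonius circle
$|x_1 - x_0|/|x_2 - x_0| = \exp[(2\alpha - 1)\ln(d/\varepsilon)]$ —
traced in closed form by `source_locus()`, with the perpendicular
bisector at $\alpha = \tfrac12$ and a direction indicator from which
flux is larger.

With $N \ge 3$ windows `recover_source()` solves
$P_i(x_0) = \alpha_i$, $i = 1..N-1$ by damped Gauss–Newton with a
finite-difference Jacobian, started from a polar grid (8 directions
$\times$ 6 log-spaced radii spanning $[d, 50d]$; the $50d$ bound is a
solver guard, configurable). Distinct roots are de-duplicated at
$10^{-4}$ and filtered by the *full* flux vector including the redundant
window: pairwise curve intersections that are not common to all curves
fail this filter, implementing the all-curves-intersect criterion. In
the noiseless round trip the source is recovered to better than
$10^{-6}$ across both geometries.

`recovery_region()` propagates flux noise: the two independent
observations are perturbed multiplicatively over a grid of
$[-\eta, \eta]^2$ (all sign corners included; the reference figure
perturbs both fluxes with a common signed $\eta$, a subset of this box)
and each perturbed system is re-inverted warm-started from the
unperturbed solution. The image point cloud and its convex hull are the
uncertainty region; its area grows steeply with source distance because
the flux-to-position map flattens as $1/L$. At large distances some
independent-sign perturbations leave the attainable flux set entirely —
the forward map is even across the boundary line, so its range is
bounded — and those grid nodes are flagged (`ok = FALSE`, region
`partial`) rather than silently dropped. `distance_map()` inverts the
three-window system over a grid of the admissible flux simplex
($P_1 + P_3 < 1$, margins masked) and reports the recovered source
distance per flux pair.

## Synthetic scenarios

`scenario_fixture()` regenerates every reference configuration in code
(nothing is downloaded or stored): the two-window half-plane sweep
(separation 1, $\varepsilon = 0.1$, source distances $L = 2, 5, 10$,
9 angles), the three- and five-window recovery layouts (windows at
$z = -1,0,1$ and $-2..2$, source $(-2, 8)$), the disk stability sweep
($R_e \in \{1.3, 2, 3\}$, two $R_o$), and a disk-in-strip demonstration.
$\varepsilon = 0.1$ is the package's reference window size — one tenth
of the window separation, a realistic receptor-to-spacing ratio, and
round-trip quantities are $\varepsilon$-consistent so inversion results
do not depend on the choice. These scenarios emulate ideal steady-state
conditions: a single fixed source, perfectly absorbing windows, no
binding kinetics, no interaction between particles, and no measurement
noise beyond what `recovery_region()` injects; passing tests therefore
validate the mathematics and the sampler, not the biology of any real
receptor system.

Test and validation problem sizes are chosen to characterize the
estimators well while keeping the default suite quick: $10^5$ samples
for distributional (chi-square) checks, $10^4$–$10^5$ trajectories per
simulation point, 400–500 Fourier modes for the spectral ground truth
(accuracy $\sim 10^{-3}$), and $10^4$ series modes for the semi-strip
identity (error $< 10^{-8}$ away from the near-diagonal).

## Numerical choices and limitations

* Points closer than $10^{-12}$ to a logarithmic singularity raise an
  error rather than returning infinities.
* Quadrature invariants (exit densities integrating to one) are enforced
  at $10^{-8}$ with adaptive quadrature; sampler agreement at
  chi-square $p > 0.01$ with $n = 10^5$.
* The well-separated-window regime is unquantified in the asymptotic
  theory; the package warns when a separation drops below
  $5\varepsilon$ and refuses below $\varepsilon$.
* The leading-order asymptotics is the package's default convention;
  its finite-$\varepsilon$ error is documented above and removable via
  `matching = "capacity"`, but the formulas remain leading-log in the
  window-interaction terms, so clustered windows are out of scope.
* Time-dependent (transient) fluxes, first-passage-time statistics and
  3D domains are out of scope.
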