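/* Compiled right-hand side for the 16-state KaiA-KaiC mass-action model.
 *
 * State: y[0..15] = the 16 KaiC states (uM), y[16] = cumulative Pi (uM).
 * Parameters (via deSolve initfunc): p[0] = total KaiA dimer (uM),
 * p[1..256] = M0 (16x16, column-major, s^-1), p[257..512] = Mb (the
 * bilinear KaiA-binding operator, s^-1 uM^-1), p[513..528] = per-state
 * hydrolysis rates (s^-1). Free KaiA is total dimer minus the 8
 * KaiA-bound states (positions 8..15). Rates are per second; the factor
 * 3600 converts to the hour-based time axis.
 */
#include <R.h>

static double kai_p[529];

void kai_init(void (*odeparms)(int *, double *))
{
    int n = 529;
    odeparms(&n, kai_p);
}

void kai_deriv(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double *M0 = kai_p + 1;
    const double *Mb = kai_p + 257;
    const double *h = kai_p + 513;
    double Afree = kai_p[0];
    double pi_rate = 0.0;
    int i, j;

    for (i = 8; i < 16; i++)
        Afree -= y[i];
    for (i = 0; i < 16; i++) {
        double s = 0.0;
        for (j = 0; j < 16; j++)
            s += (M0[i + 16 * j] + Afree * Mb[i + 16 * j]) * y[j];
        ydot[i] = 3600.0 * s;
        pi_rate += h[i] * y[i];
    }
    ydot[16] = 3600.0 * pi_rate;
}
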