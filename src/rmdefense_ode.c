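/* Compiled right-hand side for the host-phage interaction models.
 *
 * One routine serves all three model kinds through the susceptibility
 * matrix Gamma (hosts x phages):
 *   general : np = 1, Gamma is the single-column vector gamma_i
 *   parallel: np = n, Gamma diagonal (phage i infects host i only)
 *   memory  : np = n, Gamma dense (every phage infects every host)
 *
 * State y = (N, B_1..B_n, P_1..P_np). Parameter vector layout:
 *   parms[0] = n, parms[1] = np, parms[2] = S, parms[3] = phi,
 *   parms[4] = beta, parms[5] = delta_b, parms[6] = delta_p,
 *   parms[7 .. 7+n-1]           = alpha_i * (1 - c_i)   (effective uptake)
 *   parms[7+n .. 7+n+n*np-1]    = Gamma, column major
 */

#include <R.h>

#define RM_MAX_PARMS 2048    /* supports up to ~40 host populations */

static double parms_buf[RM_MAX_PARMS];

void rm_initmod(void (*odeparms)(int *, double *))
{
    int n = RM_MAX_PARMS;
    odeparms(&n, parms_buf);
}

void rm_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const int n  = (int) parms_buf[0];
    const int np = (int) parms_buf[1];
    const double S       = parms_buf[2];
    const double phi     = parms_buf[3];
    const double beta    = parms_buf[4];
    const double delta_b = parms_buf[5];
    const double delta_p = parms_buf[6];
    const double *alpha_eff = parms_buf + 7;
    const double *Gamma     = parms_buf + 7 + n;

    const double N = y[0] > 0 ? y[0] : 0;
    double growth_sum = 0, flux_sum = 0;
    int i, j;

    for (i = 0; i < np; i++) ydot[1 + n + i] = 0;

    for (i = 0; i < n; i++) {
        const double B = y[1 + i] > 0 ? y[1 + i] : 0;
        /* infection pressure on host i per cell: phi * sum_j Gamma_ij P_j */
        double lam = 0;
        for (j = 0; j < np; j++) {
            const double P = y[1 + n + j] > 0 ? y[1 + n + j] : 0;
            lam += Gamma[i + j * n] * P;
        }
        lam *= phi;
        const double growth = alpha_eff[i] * B * N;
        growth_sum += growth;
        ydot[1 + i] = growth - lam * B - delta_b * B;
        if (np == 1) {
            flux_sum += lam * B;
        } else {
            /* phage i reproduces from every infection of host i */
            ydot[1 + n + i] += beta * lam * B;
        }
    }
    ydot[0] = S - growth_sum;

    for (j = 0; j < np; j++) {
        const double P = y[1 + n + j] > 0 ? y[1 + n + j] : 0;
        if (np == 1) ydot[1 + n + j] = beta * flux_sum;
        ydot[1 + n + j] -= delta_p * P;
    }
}
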